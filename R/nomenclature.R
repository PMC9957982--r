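#' The hierarchical cerebral arterial nomenclature
#'
#' Loads the 62-branch / 20-chunk nomenclature shipped with the package (or a
#' user-edited copy). Chunk codes are `A0`-`A10` (anterior circulation plus
#' the anterior communicating artery) and `P0`-`P8` (posterior circulation);
#' branch identifiers are `<chunk>.<2-digit index>`, with single-branch
#' chunks (`A0`, `P0`, `P1`, `P2`) using the bare chunk code. Odd-numbered
#' chunks are right-sided, even-numbered left-sided (`A0`/`P0` midline).
#'
#' @param path optional path to an alternative nomenclature JSON.
#' @return A `cav_nomenclature`: list with tibbles `chunks`
#'   (code, name, side) and `branches` (code, chunk, name, provisional).
#' @export
#' @examples
#' nm <- nomenclature()
#' nrow(nm$branches)  # 62
#' nrow(nm$chunks)    # 20
nomenclature <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nomenclature.json", package = "cavlabel")
  }
  raw <- jsonlite::fromJSON(path)
  nm <- structure(
    list(
      chunks = as_tibble(raw$chunks),
      branches = as_tibble(raw$branches),
      adjacency = raw$chunk_adjacency,
      version = raw$version
    ),
    class = "cav_nomenclature"
  )
  if (nrow(nm$branches) != length(unique(nm$branches$code))) {
    abort("duplicate branch codes in nomenclature")
  }
  if (!all(nm$branches$chunk %in% nm$chunks$code)) {
    abort("nomenclature branch maps to unknown chunk")
  }
  nm
}

#' @export
print.cav_nomenclature <- function(x, ...) {
  cat("<cav_nomenclature> v", x$version, ": ", nrow(x$branches), " branches in ",
      nrow(x$chunks), " chunks\n", sep = "")
  invisible(x)
}

#' Parse branch identifiers
#'
#' Splits codes of the form `"A7.09"` into the owning chunk (`"A7"`) and the
#' integer segment index (9). Bare chunk codes of single-branch chunks parse
#' with segment index 0.
#'
#' @param codes character vector of branch identifiers.
#' @return tibble with columns `code`, `chunk`, `segment_index`.
#' @export
#' @examples
#' parse_branch_code(c("A7.09", "P0"))
parse_branch_code <- function(codes) {
  m <- regmatches(codes, regexec("^(A10|A[0-9]|P[0-8])(?:\\.([0-9]{2}))?$", codes))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    abort(paste0("malformed branch code(s): ", paste(codes[bad], collapse = ", ")))
  }
  tibble(
    code = codes,
    chunk = vapply(m, `[`, "", 2),
    segment_index = vapply(m, function(g) {
      if (g[3] == "") 0L else as.integer(g[3])
    }, 1L)
  )
}

#' Map branch codes to their owning chunk
#'
#' @param branch_codes character vector of branch identifiers.
#' @param map a [nomenclature()] object.
#' @return character vector of chunk codes (same length).
#' @export
chunk_of <- function(branch_codes, map = nomenclature()) {
  idx <- match(branch_codes, map$branches$code)
  if (anyNA(idx[!is.na(branch_codes)])) {
    unknown <- unique(branch_codes[is.na(idx) & !is.na(branch_codes)])
    abort(paste0("unknown branch code(s): ", paste(unknown, collapse = ", ")))
  }
  map$branches$chunk[idx]
}

#' Chunk laterality helpers
#'
#' @param chunk_codes character vector of chunk codes.
#' @param map a [nomenclature()] object.
#' @return `chunk_side`: "right", "left" or "midline"; `chunk_mirror`: the
#'   contralateral chunk code (midline chunks map to themselves).
#' @export
chunk_side <- function(chunk_codes, map = nomenclature()) {
  map$chunks$side[match(chunk_codes, map$chunks$code)]
}

#' @rdname chunk_side
#' @export
chunk_mirror <- function(chunk_codes, map = nomenclature()) {
  pre <- substr(chunk_codes, 1, 1)
  num <- as.integer(substring(chunk_codes, 2))
  mirrored <- ifelse(num == 0, num, ifelse(num %% 2 == 1, num + 1L, num - 1L))
  out <- paste0(pre, mirrored)
  out[!out %in% map$chunks$code] <- chunk_codes[!out %in% map$chunks$code]
  out
}
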