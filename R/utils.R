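`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates `code` on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Region labels encode hemisphere side as "<parcel>|<side>"; unsplit labels
# are the bare parcel id.
make_region_label <- function(parcel_id, side = "unsplit") {
  ifelse(side == "unsplit", parcel_id, paste0(parcel_id, "|", side))
}

#' Parse region labels into parcel and hemisphere side
#'
#' Column labels of a projection matrix are either a bare parcel id
#' (side `"unsplit"`) or `"<parcel>|<side>"` with side `"ipsi"` or
#' `"contra"`.
#'
#' @param labels character vector of region labels.
#' @return data frame with columns `label`, `parcel_id`, `side`.
#' @export
parse_region_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  parcel <- vapply(parts, `[`, character(1), 1L)
  side <- vapply(parts, function(p) {
    if (length(p) > 1L) p[[2L]] else "unsplit"
  }, character(1))
  bad <- !side %in% c("ipsi", "contra", "unsplit")
  if (any(bad)) {
    stop("invalid hemisphere side in region label(s): ",
         paste(labels[bad], collapse = ", "))
  }
  data.frame(label = labels, parcel_id = parcel, side = side,
             stringsAsFactors = FALSE)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
  invisible(x)
}
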