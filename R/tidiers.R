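#' Broom-style tidiers
#'
#' `tidy()` turns ordering and universal-set objects into m-mer-level
#' tibbles; `glance()` gives one-row summaries. Re-exported generics keep
#' pipelines `library(kmerbin)`-only.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidiers
#' @param x A `min_ordering` or `universal_set`.
#' @param codes m-mer codes to rank (default: all 4^m, allowed for m <= 8).
#' @param ... Unused.
#' @export
tidy.min_ordering <- function(x, codes = NULL, ...) {
  if (is.null(codes)) {
    if (x$m > 8L) stop("enumerating all 4^m m-mers is limited to m <= 8; ",
                       "pass codes explicitly")
    codes <- 0:(4^x$m - 1)
  }
  tibble::tibble(
    code = as.numeric(codes),
    mmer = decode_mer(codes, x$m),
    rank = mmer_rank(x, codes)
  ) |> dplyr::arrange(.data$rank)
}

#' @rdname tidiers
#' @export
glance.min_ordering <- function(x, ...) {
  tibble::tibble(name = x$name, m = x$m, span = x$span,
                 seed = x$meta$seed %||% NA_integer_,
                 uhs_size = x$meta$uhs_size %||% NA_integer_)
}

#' @rdname tidiers
#' @export
tidy.universal_set <- function(x, ...) {
  tibble::tibble(code = x$members, mmer = decode_mer(x$members, x$m))
}

#' @rdname tidiers
#' @export
glance.universal_set <- function(x, ...) {
  tibble::tibble(m = x$m, k = x$k, size = length(x$members),
                 source = x$source)
}

#' @importFrom rlang %||%
NULL
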