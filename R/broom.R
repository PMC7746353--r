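#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidiers for differential-expression results
#'
#' `tidy()` returns the per-fragment table as a plain tibble; `glance()`
#' returns a one-row summary (numbers tested, significant, up- and
#' down-regulated, and the gates applied).
#'
#' @param x A `tsrna_diff` from [diff_test()].
#' @param ... Ignored.
#' @method tidy tsrna_diff
#' @export
tidy.tsrna_diff <- function(x, ...) {
  out <- x
  attributes(out)[c("groups", "fc_thresh", "alpha")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname tidy.tsrna_diff
#' @method glance tsrna_diff
#' @export
glance.tsrna_diff <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2fc > 0),
    n_down = sum(x$significant & x$log2fc < 0),
    fc_thresh = attr(x, "fc_thresh") %||% NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Tidiers for enrichment results
#'
#' `tidy()` strips the class; `glance()` summarises the run (terms
#' tested, terms passing, list and universe sizes).
#'
#' @param x A `tsrna_enrich` from [enrich()].
#' @param ... Ignored.
#' @method tidy tsrna_enrich
#' @export
tidy.tsrna_enrich <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname tidy.tsrna_enrich
#' @method glance tsrna_enrich
#' @export
glance.tsrna_enrich <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_pass = sum(x$pass),
    list_size = if (nrow(x)) x$list_size[1] else NA_integer_,
    universe_size = if (nrow(x)) x$universe_size[1] else NA_integer_
  )
}
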