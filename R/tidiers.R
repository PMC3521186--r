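#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an H-BOP fit
#'
#' `tidy()` returns one row per fragment with its assigned group;
#' `glance()` returns a one-row summary of the fit.
#'
#' @param x an `hbop_fit` from [hbop_phase()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hbop_fit <- function(x, ...) {
  tibble::tibble(
    row = seq_along(x$partition),
    id = x$row_ids,
    group = x$partition
  )
}

#' @rdname tidy.hbop_fit
#' @export
glance.hbop_fit <- function(x, ...) {
  tibble::tibble(
    sc = x$score$errors_corrected,
    sd = x$score$fragments_cut,
    sp = x$score$partition_score,
    w = x$w,
    k = x$k,
    n_fragments = length(x$partition),
    n_sites = length(x$haplotype$h1),
    n_phased = sum(x$haplotype$phased)
  )
}

#' Tidy a per-block H-BOP fit
#'
#' `tidy()` returns the per-block result table; `glance()` the genome-wide
#' summary.
#'
#' @param x an `hbop_blocks_fit` from [phase_blocks()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hbop_blocks_fit <- function(x, ...) {
  dplyr::select(x$blocks, -"sites")
}

#' @rdname tidy.hbop_blocks_fit
#' @export
glance.hbop_blocks_fit <- function(x, ...) {
  tibble::tibble(
    sc = x$score$errors_corrected,
    sd = x$score$fragments_cut,
    sp = x$score$partition_score,
    w = x$w,
    k = x$k,
    n_blocks = nrow(x$blocks),
    n_phaseable = sum(x$blocks$phaseable),
    n_sites = length(x$haplotype$h1),
    n_phased = sum(x$haplotype$phased)
  )
}
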