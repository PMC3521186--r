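#' Run a simulate–phase–evaluate experiment grid
#'
#' For every combination of `e`, `m` and `l` (or every row of a `cells`
#' tibble), simulates `replicates` datasets, phases each per block with
#' H-BOP and evaluates it against the simulated truth. Replicate `j` of
#' every cell uses seed `base_seed + j`, so a rerun with the same base seed
#' reproduces the table bit for bit, and cells differing only in a
#' parameter see matched random streams.
#'
#' @param e,m,l vectors of sequencing error rates, fragment counts and mean
#'   fragment lengths; their full crossing forms the grid. Ignored when
#'   `cells` is given.
#' @param cells optional tibble with columns `e`, `m`, `l`, one row per
#'   grid cell.
#' @param n haplotype length (default 100).
#' @param g gap rate (default 0.1).
#' @param w,k H-BOP parameters (defaults 0.1 and 8).
#' @param replicates experiments per cell (default 100).
#' @param base_seed base RNG seed (default 1).
#' @return a tibble of class `hbop_experiment` with one row per replicate:
#'   the cell parameters, `replicate`, `seed`, `call_coverage`, `sc`, `sd`,
#'   `sp`, `switch_errors`, `phased_length`, `switch_error_rate`, `qan50`,
#'   `n_blocks` and `runtime` (seconds, hardware-dependent).
#' @examples
#' raw <- run_experiment(e = 0.02, m = 60, l = 3, n = 50, replicates = 3)
#' summarize_experiment(raw)
#' @export
run_experiment <- function(e = 0.01, m = 140, l = 3, cells = NULL,
                           n = 100, g = 0.1, w = 0.1, k = 8,
                           replicates = 100, base_seed = 1) {
  if (is.null(cells)) {
    cells <- tidyr::expand_grid(e = e, m = m, l = l)
  }
  stopifnot(all(c("e", "m", "l") %in% names(cells)))
  rows <- purrr::pmap(cells, function(e, m, l, ...) {
    purrr::map(seq_len(replicates), function(j) {
      seed <- base_seed + j
      t0 <- proc.time()[["elapsed"]]
      sim <- simulate_fragments(n = n, m = m, l = l, e = e, g = g,
        seed = seed)
      fit <- phase_blocks(sim$matrix, w = w, k = k)
      ev <- evaluate_phasing(sim$truth, fit$haplotype, fit)
      dplyr::bind_cols(
        tibble::tibble(
          e = e, m = m, l = l, n = n, g = g, w = w, k = k,
          replicate = j, seed = seed,
          call_coverage = sim$call_coverage,
          sc = fit$score$errors_corrected,
          sd = fit$score$fragments_cut,
          sp = fit$score$partition_score
        ),
        ev,
        tibble::tibble(runtime = proc.time()[["elapsed"]] - t0)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("hbop_experiment", class(out))
  out
}

#' Summarize an experiment table
#'
#' Collapses replicate rows into per-cell means and standard errors of the
#' accuracy metrics.
#'
#' @param raw the tibble returned by [run_experiment()].
#' @return a tibble with one row per `(e, m, l)` cell: replicate counts,
#'   means and standard errors of switch errors and phased length, mean
#'   switch error rate, mean call coverage and mean runtime.
#' @export
summarize_experiment <- function(raw) {
  se <- function(x) stats::sd(x) / sqrt(length(x))
  raw |>
    dplyr::group_by(.data$e, .data$m, .data$l, .data$n, .data$g,
      .data$w, .data$k) |>
    dplyr::summarize(
      replicates = dplyr::n(),
      mean_switch_errors = mean(.data$switch_errors),
      se_switch_errors = se(.data$switch_errors),
      mean_phased_length = mean(.data$phased_length),
      se_phased_length = se(.data$phased_length),
      mean_switch_error_rate = mean(.data$switch_error_rate, na.rm = TRUE),
      mean_call_coverage = mean(.data$call_coverage),
      mean_runtime = mean(.data$runtime),
      .groups = "drop"
    )
}
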