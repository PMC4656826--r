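#' Tidy the per-replicate table of an experiment result
#'
#' @param x An `sge_fixation_result` or `sge_modifier_result`.
#' @param ... Unused.
#' @return A tibble with one row per replicate.
#' @method tidy sge_fixation_result
#' @export
tidy.sge_fixation_result <- function(x, ...) x$replicates

#' @rdname tidy.sge_fixation_result
#' @method tidy sge_modifier_result
#' @export
tidy.sge_modifier_result <- function(x, ...) x$replicates

#' One-row summary of an experiment result
#'
#' @param x An `sge_fixation_result` or `sge_modifier_result`.
#' @param ... Unused.
#' @return A one-row tibble of the aggregate quantities.
#' @method glance sge_fixation_result
#' @export
glance.sge_fixation_result <- function(x, ...) {
  tibble(N = x$params$N, S = x$params$S, sigma_BB = x$params$sigma_BB,
         h1 = x$params$h1, t_switch = x$params$t_switch,
         n_copies_a = x$n_copies_a,
         n_replicates = x$n_meta * x$params$n_replicates,
         n_meta = x$n_meta,
         n_fixed = x$n_fixed, n_lost = x$n_lost,
         n_extinct = x$n_extinct, n_censored = x$n_censored,
         initial_frequency = x$initial_frequency,
         fixation_probability = x$fixation_probability,
         sd_fixation = x$sd_fixation,
         relative_fixation = x$relative_fixation)
}

#' @rdname glance.sge_fixation_result
#' @method glance sge_modifier_result
#' @export
glance.sge_modifier_result <- function(x, ...) {
  tibble(N = x$params$N, S = x$params$S, sigma_BB = x$params$sigma_BB,
         h1 = x$params$h1, h2 = x$params$h2, hb = x$params$hb,
         t_switch = x$params$t_switch,
         selection_mode = x$params$selection_mode,
         init = x$init,
         n_generations = x$params$n_generations,
         n_replicates = x$params$n_replicates,
         n_extinct = x$n_extinct,
         mean_final_freq_A = x$mean_final_freq_A,
         mean_final_freq_B = x$mean_final_freq_B,
         se_final_freq_B = x$se_final_freq_B,
         advantage = x$advantage)
}

#' @export
print.sge_fixation_result <- function(x, ...) {
  cat("<sge_fixation_result>\n")
  cat(sprintf("  N = %d, S = %g, sigma_BB = %g, initial copies of a = %d\n",
              x$params$N, x$params$S, x$params$sigma_BB,
              as.integer(x$n_copies_a)))
  cat(sprintf("  %d replicates: %d fixed, %d lost, %d extinct, %d censored\n",
              nrow(x$replicates), x$n_fixed, x$n_lost, x$n_extinct,
              x$n_censored))
  cat(sprintf("  P(fix a) = %.4g  (relative to neutral %.4g: %.4g)\n",
              x$fixation_probability, x$initial_frequency,
              x$relative_fixation))
  invisible(x)
}

#' @export
print.sge_modifier_result <- function(x, ...) {
  cat("<sge_modifier_result>\n")
  cat(sprintf("  N = %d, S = %g, sigma_BB = %g, T = %s, mode = %s, init = %s\n",
              x$params$N, x$params$S, x$params$sigma_BB,
              format(x$params$t_switch), x$params$selection_mode, x$init))
  cat(sprintf("  %d replicates (%d extinct), %d generations\n",
              x$params$n_replicates, x$n_extinct, x$params$n_generations))
  cat(sprintf("  mean final freq(B) = %.4f (se %.4f) -> enhanced SGE %s\n",
              x$mean_final_freq_B, x$se_final_freq_B,
              if (x$advantage) "advantageous" else "not advantageous"))
  invisible(x)
}

#' Plot experiment results
#'
#' `autoplot()` methods: a histogram of final modifier-allele frequencies
#' for modifier experiments (with trajectories, a per-replicate frequency
#' trace), an outcome bar chart for fixation experiments, allele-frequency
#' and heterozygosity traces for a single trajectory, and a heat-map over
#' the first two varying grid axes for sweeps.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sge_modifier_result
#' @export
autoplot.sge_modifier_result <- function(object, ...) {
  if (!is.null(object$trajectories)) {
    return(
      ggplot2::ggplot(object$trajectories,
                      ggplot2::aes(x = .data$generation, y = .data$freq_B,
                                   group = .data$replicate)) +
        ggplot2::geom_line(alpha = 0.3) +
        ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
        ggplot2::labs(x = "generation", y = "frequency of allele B") +
        ggplot2::ylim(0, 1)
    )
  }
  dat <- dplyr::filter(object$replicates, !.data$extinct)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$final_freq_B)) +
    ggplot2::geom_histogram(bins = 21, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "final frequency of allele B", y = "replicates")
}

#' @rdname autoplot.sge_modifier_result
#' @method autoplot sge_fixation_result
#' @export
autoplot.sge_fixation_result <- function(object, ...) {
  dat <- dplyr::count(object$replicates, .data$outcome)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "replicates")
}

#' @rdname autoplot.sge_modifier_result
#' @method autoplot sge_trajectory
#' @export
autoplot.sge_trajectory <- function(object, ...) {
  dat <- tidyr::pivot_longer(as_tibble(object),
                             c("freq_A", "freq_B"),
                             names_to = "locus", values_to = "frequency")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation,
                                    y = .data$frequency,
                                    colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "allele frequency")
}

#' @rdname autoplot.sge_modifier_result
#' @param x,y Grid columns for the heat-map axes; default the first two
#'   columns of the sweep grid that take more than one value.
#' @method autoplot sge_sweep
#' @export
autoplot.sge_sweep <- function(object, x = NULL, y = NULL, ...) {
  kind <- attr(object, "kind")
  fill <- if (identical(kind, "fixation")) "relative_fixation"
          else "mean_final_freq_B"
  axis_candidates <- setdiff(names(object),
                             c("cell_seed", "n_replicates_run", fill,
                               "se_final_freq_B", "advantage", "n_extinct",
                               "fixation_probability", "relative_fixation",
                               "n_informative"))
  varying <- axis_candidates[vapply(object[axis_candidates],
                                    function(v) length(unique(v)) > 1L,
                                    TRUE)]
  if (is.null(x)) x <- varying[1]
  if (is.null(y)) y <- varying[2]
  if (is.na(x) || is.na(y)) {
    abort("Sweep has fewer than two varying axes; supply `x` and `y`.")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data[[x]]),
                               y = factor(.data[[y]]),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = if (kind == "modifier") c(0, 1)
                                          else NULL) +
    ggplot2::labs(x = x, y = y, fill = fill)
}
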