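#' Plot a critical curve
#'
#' The MIE boundary in the (parameter, turnover) plane: populations below the
#' curve grow, populations above it go extinct through missegregation flux
#' into nonviable karyotypes.
#'
#' @param object A [critical_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.critical_curve <- function(object, ...) {
  pname <- attr(object, "parameter_name")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter,
                                       y = .data$critical_turnover)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = switch(pname, beta = "missegregation rate β",
                 theta1 = "linear kernel slope θ₁",
                 theta2 = "sinusoidal kernel amplitude θ₂", pname),
      y = "critical turnover μ/λ",
      title = "Missegregation-induced extinction boundary",
      subtitle = paste0(attr(object, "assumptions"), " rates")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a quasi-steady-state trajectory
#'
#' Karyotype composition over time at the convergence checkpoints; the
#' population total evolves separately (log scale, see `glance()`).
#'
#' @param object A [simulate_to_qss()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qss_result <- function(object, ...) {
  traj <- object$trajectory
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data$proportion,
                                     group = .data$state,
                                     color = factor(.data$state))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "karyotype proportion",
                  color = "state",
                  title = sprintf("Karyotype composition (%s)",
                                  object$classification)) +
    ggplot2::theme_minimal()
}

#' Plot a shift distribution
#'
#' @param object A [shift_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shift_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$prob)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(
      x = "copy-number shift t", y = "P(t | i)",
      title = sprintf("Daughter shift distribution (i = %d, β = %g)",
                      attr(object, "parent_copies"), attr(object, "beta"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ploidy-estimate error profile
#'
#' The rounding-error `E_x` for each candidate number `x` of assumed-diploid
#' chromosomes, with the chosen `x*` marked.
#'
#' @param object An [estimate_ploidy()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ploidy_estimate <- function(object, ...) {
  ggplot2::ggplot(object$error_profile,
                  ggplot2::aes(x = .data$x, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$x_star, linetype = "dashed") +
    ggplot2::labs(x = "assumed-diploid chromosomes x",
                  y = "rounding error E_x",
                  title = sprintf("Ploidy estimation: x* = %d, bias = %.3g",
                                  object$x_star, object$bias)) +
    ggplot2::theme_minimal()
}
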