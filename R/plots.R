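# ggplot2 visualisations of the main result types.

#' Secreted fraction versus genome size by lifestyle
#'
#' @param per_genome Per-genome tibble from [secretome_summary()] (or an
#'   `sp_run_report`, whose secretome table is used).
#' @return A ggplot object.
#' @export
plot_secretome <- function(per_genome) {
  if (inherits(per_genome, "sp_run_report")) {
    per_genome <- per_genome$secretome$per_genome
  }
  ggplot2::ggplot(per_genome,
                  ggplot2::aes(x = .data$genome_size, y = .data$fraction_sp,
                               colour = .data$lifestyle)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed") +
    ggplot2::labs(x = "genome size (genes)",
                  y = "fraction of proteins with a signal peptide",
                  colour = "lifestyle") +
    ggplot2::theme_minimal()
}

#' Sequence identity distributions by pair class
#'
#' @param identities Result of [identity_distributions()] (or an
#'   `sp_run_report`).
#' @return A ggplot object.
#' @export
plot_identity_distributions <- function(identities) {
  if (inherits(identities, "sp_run_report")) identities <- identities$identities
  ggplot2::ggplot(identities$pairs,
                  ggplot2::aes(x = .data$identity, fill = .data$pair_class)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "pairwise sequence identity", y = "pairs",
                  fill = "pair class") +
    ggplot2::theme_minimal()
}

#' Length-ratio histogram of event mechanisms
#'
#' @param mechanism Result of [mechanism_summary()] (or an `sp_run_report`).
#' @return A ggplot object.
#' @export
plot_lr_histogram <- function(mechanism) {
  if (inherits(mechanism, "sp_run_report")) mechanism <- mechanism$mechanism
  ggplot2::ggplot(mechanism$mechanisms,
                  ggplot2::aes(x = .data$lr, fill = .data$type)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, alpha = 0.7) +
    ggplot2::labs(x = "length ratio (non-SP N-terminus / signal peptide)",
                  y = "events", fill = "event type") +
    ggplot2::theme_minimal()
}

#' Autoplot method for run reports
#'
#' @param object An `sp_run_report`.
#' @param type One of `"secretome"`, `"identity"`, `"lr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sp_run_report
#' @export
autoplot.sp_run_report <- function(object, type = c("secretome", "identity", "lr"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
         secretome = plot_secretome(object),
         identity = plot_identity_distributions(object),
         lr = plot_lr_histogram(object))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
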