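# S3 methods for fitted velode models

#' @export
print.velode <- function(x, ...) {
  n <- length(x$t); p <- ncol(x$velocity$Vs)
  cat("velode fit:", n, "cells x", p, "genes\n")
  cat(sprintf("  epochs run: %d; final objective: %.4f\n",
              max(x$loss_history$epoch),
              x$loss_history$total[nrow(x$loss_history)]))
  cat(sprintf("  direction flipped: %s; retrained: %s\n",
              x$flipped, x$retrained))
  invisible(x)
}

#' @export
summary.velode <- function(object, ...) {
  rates <- kinetic_rates(object$state)
  out <- list(
    n_cells = length(object$t),
    n_genes = ncol(object$velocity$Vs),
    epochs = max(object$loss_history$epoch),
    final_losses = object$loss_history[nrow(object$loss_history), ],
    flipped = object$flipped,
    retrained = object$retrained,
    t_range = range(object$t),
    beta_quartiles = stats::quantile(rates$beta, c(0.25, 0.5, 0.75)),
    gamma_quartiles = stats::quantile(rates$gamma, c(0.25, 0.5, 0.75))
  )
  class(out) <- "summary.velode"
  out
}

#' @export
print.summary.velode <- function(x, ...) {
  cat("velode model summary\n")
  cat(sprintf("  %d cells, %d genes, %d epochs\n",
              x$n_cells, x$n_genes, x$epochs))
  cat(sprintf("  pseudotime range: [%.3f, %.3f]\n",
              x$t_range[1], x$t_range[2]))
  cat(sprintf("  direction flipped: %s; retrained: %s\n",
              x$flipped, x$retrained))
  cat("  splicing rate beta quartiles:",
      sprintf("%.3f", x$beta_quartiles), "\n")
  cat("  degradation rate gamma quartiles:",
      sprintf("%.3f", x$gamma_quartiles), "\n")
  fl <- x$final_losses
  cat(sprintf("  final losses: lt1=%.3f lt2=%.3f lt3=%.3f lv1=%.3f lv2=%.3f total=%.3f\n",
              fl$lt1, fl$lt2, fl$lt3, fl$lv1, fl$lv2, fl$total))
  invisible(x)
}

#' Per-gene kinetic parameters of a fitted model
#' @param object a fitted \code{velode} model.
#' @param ... unused.
#' @return data.frame(gene, beta, gamma, gamma_beta_ratio).
#' @export
coef.velode <- function(object, ...) {
  rates <- kinetic_rates(object$state)
  data.frame(gene = object$data$gene_ids, beta = rates$beta,
             gamma = rates$gamma,
             gamma_beta_ratio = rates$gamma / rates$beta,
             row.names = NULL)
}

#' Model reconstruction of the input features
#' @param object a fitted \code{velode} model.
#' @param path decode the ODE-evolved latent state (\code{"zt"}, default) or
#'   the posterior mean (\code{"z"}).
#' @param ... unused.
#' @export
fitted.velode <- function(object, path = c("zt", "z"), ...) {
  path <- match.arg(path)
  decode(object$state, if (path == "zt") object$Zt else object$Z)
}

#' Reconstruction residuals X - Xhat
#' @inheritParams fitted.velode
#' @export
residuals.velode <- function(object, path = c("zt", "z"), ...) {
  feature_matrix(object$data) - fitted.velode(object, path = path)
}

#' Diagnostic plots for a fitted model
#'
#' \code{type = "loss"} draws the training objective per epoch;
#' \code{type = "phase"} draws the unspliced/spliced phase portrait of one
#' gene colored by velocity sign; \code{type = "pseudotime"} draws pseudotime
#' against the dataset embedding (when present) or against cell index.
#'
#' @param x a fitted \code{velode} model.
#' @param type one of \code{"loss"}, \code{"phase"}, \code{"pseudotime"}.
#' @param gene gene index or name for the phase portrait.
#' @param ... passed to the underlying plot call.
#' @export
plot.velode <- function(x, type = c("loss", "phase", "pseudotime"),
                        gene = 1L, ...) {
  type <- match.arg(type)
  if (type == "loss") {
    graphics::plot(x$loss_history$epoch, -x$loss_history$total, type = "l",
                   xlab = "epoch", ylab = "objective (-total)", ...)
  } else if (type == "phase") {
    if (is.character(gene)) gene <- match(gene, x$data$gene_ids)
    s <- x$data$S[, gene]; u <- x$data$U[, gene]
    up <- x$velocity$Vs[, gene] > 0
    graphics::plot(s, u, col = ifelse(up, "firebrick", "steelblue"),
                   pch = 16, cex = 0.6,
                   xlab = "spliced", ylab = "unspliced",
                   main = x$data$gene_ids[gene], ...)
    graphics::legend("topleft", pch = 16, col = c("firebrick", "steelblue"),
                     legend = c("Vs > 0", "Vs <= 0"), bty = "n")
  } else {
    if (!is.null(x$data$embedding)) {
      cols <- grDevices::hcl.colors(100, "viridis")
      idx <- pmax(1L, ceiling(99 * (x$t - min(x$t)) /
                                max(1e-12, diff(range(x$t)))) )
      graphics::plot(x$data$embedding, col = cols[idx], pch = 16, cex = 0.6,
                     xlab = "emb 1", ylab = "emb 2", ...)
    } else {
      graphics::plot(seq_along(x$t), x$t, xlab = "cell", ylab = "pseudotime",
                     pch = 16, cex = 0.6, ...)
    }
  }
  invisible(x)
}
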