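# Wrap-aware mean absolute angular error, pooled and per
# secondary-structure class.

# shorter-arc absolute difference in degrees
angle_abs_diff <- function(p, e) {
  d <- abs(p - e) %% 360
  pmin(d, 360 - d)
}

#' Wrap-aware mean absolute error of predicted torsions
#'
#' Pools `min(|P - E|, 360 - |P - E|)` over every residue that is
#' unmasked in both the prediction and the reference, separately for phi
#' and psi. Masked residues are excluded from both the numerator and the
#' residue count.
#'
#' @param pred A `torsion_series` or list of them.
#' @param ref The matching reference series (same lengths).
#' @return An `eval_report`: list with `mae_phi`, `mae_psi`, `n_chains`,
#'   `n_phi`, `n_psi`, and `per_chain` (tibble with per-chain MAEs and
#'   residue counts).
#' @export
mae <- function(pred, ref) {
  if (inherits(pred, "torsion_series")) pred <- list(pred)
  if (inherits(ref, "torsion_series")) ref <- list(ref)
  stopifnot(length(pred) == length(ref))
  per <- vector("list", length(pred))
  for (i in seq_along(pred)) {
    p <- pred[[i]]; e <- ref[[i]]
    if (nrow(p) != nrow(e)) {
      stop("chain ", i, ": prediction has ", nrow(p),
           " residues but reference has ", nrow(e))
    }
    mphi <- p$phi_mask & e$phi_mask
    mpsi <- p$psi_mask & e$psi_mask
    dphi <- angle_abs_diff(p$phi[mphi], e$phi[mphi])
    dpsi <- angle_abs_diff(p$psi[mpsi], e$psi[mpsi])
    per[[i]] <- tibble::tibble(
      chain = i, n_phi = sum(mphi), n_psi = sum(mpsi),
      sum_phi = sum(dphi), sum_psi = sum(dpsi),
      mae_phi = if (sum(mphi)) mean(dphi) else NA_real_,
      mae_psi = if (sum(mpsi)) mean(dpsi) else NA_real_)
  }
  per <- dplyr::bind_rows(per)
  n_phi <- sum(per$n_phi); n_psi <- sum(per$n_psi)
  if (n_phi + n_psi == 0) stop("no unmasked residues to evaluate")
  structure(list(
    mae_phi = if (n_phi) sum(per$sum_phi) / n_phi else NA_real_,
    mae_psi = if (n_psi) sum(per$sum_psi) / n_psi else NA_real_,
    n_chains = length(pred), n_phi = n_phi, n_psi = n_psi,
    per_chain = per
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d chains: MAE(phi) %.2f deg (n=%d), MAE(psi) %.2f deg (n=%d)\n",
              x$n_chains, x$mae_phi, x$n_phi, x$mae_psi, x$n_psi))
  invisible(x)
}

#' Per-secondary-structure-class MAE
#'
#' Restricts the wrap-aware MAE to residues of each Q8 (or Q3) class.
#' Classes with no unmasked residues are reported as missing (`NA`), not
#' zero.
#'
#' @param pred,ref As in [mae()].
#' @param labels Per-residue class strings (one string per chain, length
#'   matching the chain).
#' @param classes Class alphabet (default Q8: G, H, I, T, E, B, S, C).
#' @return A tibble with one row per class: `class`, `n_phi`, `n_psi`,
#'   `mae_phi`, `mae_psi`.
#' @export
mae_by_class <- function(pred, ref, labels,
                         classes = c("G", "H", "I", "T", "E", "B", "S", "C")) {
  if (inherits(pred, "torsion_series")) pred <- list(pred)
  if (inherits(ref, "torsion_series")) ref <- list(ref)
  labels <- lapply(labels, function(s) {
    if (is.character(s) && length(s) == 1L && nchar(s) > 1L) {
      strsplit(s, "")[[1]]
    } else as.character(s)
  })
  stopifnot(length(labels) == length(pred))
  acc <- stats::setNames(
    rep(list(list(sp = 0, np = 0L, ss = 0, ns = 0L)), length(classes)), classes)
  for (i in seq_along(pred)) {
    p <- pred[[i]]; e <- ref[[i]]; lab <- labels[[i]]
    if (length(lab) != nrow(p)) {
      stop("chain ", i, ": ", length(lab), " labels for ", nrow(p), " residues")
    }
    for (cl in classes) {
      at <- lab == cl
      mphi <- at & p$phi_mask & e$phi_mask
      mpsi <- at & p$psi_mask & e$psi_mask
      acc[[cl]]$sp <- acc[[cl]]$sp + sum(angle_abs_diff(p$phi[mphi], e$phi[mphi]))
      acc[[cl]]$np <- acc[[cl]]$np + sum(mphi)
      acc[[cl]]$ss <- acc[[cl]]$ss + sum(angle_abs_diff(p$psi[mpsi], e$psi[mpsi]))
      acc[[cl]]$ns <- acc[[cl]]$ns + sum(mpsi)
    }
  }
  tibble::tibble(
    class = classes,
    n_phi = vapply(acc, function(a) a$np, integer(1)),
    n_psi = vapply(acc, function(a) a$ns, integer(1)),
    mae_phi = vapply(acc, function(a) if (a$np) a$sp / a$np else NA_real_,
                     numeric(1)),
    mae_psi = vapply(acc, function(a) if (a$ns) a$ss / a$ns else NA_real_,
                     numeric(1)))
}

#' Circular mean of angles in degrees
#'
#' @param x Angles in degrees.
#' @return The circular mean in `[-180, 180)`.
#' @export
circular_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Constant predictor at the circular mean of training angles
#'
#' The baseline the network must beat: predicts the circular mean phi and
#' psi of a training set at every position.
#'
#' @param train_torsions List of training `torsion_series`.
#' @param ref_torsions List of reference series to imitate in shape.
#' @return List of `torsion_series` predictions.
#' @export
circular_mean_predictor <- function(train_torsions, ref_torsions) {
  all_phi <- unlist(lapply(train_torsions, function(t) t$phi[t$phi_mask]))
  all_psi <- unlist(lapply(train_torsions, function(t) t$psi[t$psi_mask]))
  mphi <- circular_mean(all_phi)
  mpsi <- circular_mean(all_psi)
  lapply(ref_torsions, function(r) {
    new_torsion_series(rep(mphi, nrow(r)), rep(mpsi, nrow(r)),
                       r$phi_mask, r$psi_mask, aa = r$aa)
  })
}

# ---- broom-style and plotting methods ----------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-chain evaluation rows
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-chain tibble.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$per_chain

#' One-row evaluation summary
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble with pooled MAEs and counts.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(mae_phi = x$mae_phi, mae_psi = x$mae_psi,
                 n_chains = x$n_chains, n_phi = x$n_phi, n_psi = x$n_psi)
}

#' Tidy training history
#'
#' @param x A `train_state`.
#' @param ... Unused.
#' @return Tibble of per-step training loss joined with validation MAE
#'   where evaluated.
#' @exportS3Method generics::tidy
tidy.train_state <- function(x, ...) {
  dplyr::left_join(x$loss_history, x$val_history, by = "step")
}

#' One-row training summary
#'
#' @param x A `train_state`.
#' @param ... Unused.
#' @return A one-row tibble: steps run, final training MSE, best
#'   validation MAE and the step it occurred at.
#' @exportS3Method generics::glance
glance.train_state <- function(x, ...) {
  tibble::tibble(steps = nrow(x$loss_history),
                 final_mse = x$loss_history$mse[nrow(x$loss_history)],
                 best_val_mae = x$best_val_mae, best_step = x$best_step)
}

#' Plot training curves
#'
#' @param object A `train_state`.
#' @param ... Unused.
#' @return A ggplot of training MSE and validation MAE over steps.
#' @exportS3Method ggplot2::autoplot
autoplot.train_state <- function(object, ...) {
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$step, y = .data$mse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = object$val_history,
                        ggplot2::aes(y = .data$mae / 180),
                        colour = "firebrick", size = 0.8) +
    ggplot2::scale_y_continuous(
      "training MSE",
      sec.axis = ggplot2::sec_axis(~ . * 180, name = "validation MAE (deg)")) +
    ggplot2::labs(x = "optimizer step") +
    ggplot2::theme_minimal()
}

#' Ramachandran plot of a torsion series
#'
#' @param object A `torsion_series`.
#' @param ... Unused.
#' @return A ggplot scatter of (phi, psi) over valid residues.
#' @exportS3Method ggplot2::autoplot
autoplot.torsion_series <- function(object, ...) {
  df <- object[object$phi_mask & object$psi_mask, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi~"(deg)"), y = expression(psi~"(deg)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of one basin-potential map
#'
#' @param object A `basin_potential`.
#' @param key Map key (a center residue letter or triplet key).
#' @param ... Unused.
#' @return A ggplot heatmap over the 72 x 72 (phi, psi) grid.
#' @exportS3Method ggplot2::autoplot
autoplot.basin_potential <- function(object, key = NULL, ...) {
  maps <- c(object$center_maps, object$triplet_maps)
  if (is.null(key)) key <- names(maps)[[1]]
  m <- maps[[key]]
  if (is.null(m)) stop("no map for key '", key, "'")
  centers <- seq(-180 + object$bin_width / 2, 180 - object$bin_width / 2,
                 by = object$bin_width)
  df <- expand.grid(phi = centers, psi = centers)
  df$p <- as.vector(m)  # column-major: phi varies fastest, matching rows
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "probability") +
    ggplot2::labs(title = paste("basin map:", key),
                  x = expression(phi~"(deg)"), y = expression(psi~"(deg)")) +
    ggplot2::theme_minimal()
}
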