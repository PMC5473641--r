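# Conservation-onset dating on a stem branch. The model: before the onset
# age T the element evolved neutrally (rate r subs/site/Myr); after T it
# evolved at the conserved rate rho * r. The element-specific stem branch
# length then determines T in closed form, and a column bootstrap supplies
# the standard error.

#' Expected element-specific stem branch length under a piecewise clock
#'
#' `E[b](T) = r * (t0 - T) + rho * r * (T - t1)`: strictly decreasing in T
#' for `rho < 1`.
#'
#' @param t0,t1 Stem top/bottom ages in Myr (`t1 < t0`).
#' @param r Neutral substitution rate (subs/site/Myr), > 0.
#' @param rho Conserved branch scale in (0, 1).
#' @param T Onset age in `[t1, t0]`.
#' @return Expected stem branch length in substitutions per site.
#' @export
expected_stem_length <- function(t0, t1, r, rho, T) {
  stopifnot(t1 < t0, r > 0, rho > 0)
  if (any(T < t1 - 1e-9) || any(T > t0 + 1e-9))
    stop("onset T outside [t1, t0]")
  r * (t0 - T) + rho * r * (T - t1)
}

#' Invert the expected stem length for the onset age
#'
#' Closed-form inversion `T = (r*t0 - rho*r*t1 - b) / (r*(1 - rho))`,
#' clamped to `[t1, t0]` with a flag when the observed length falls
#' outside the attainable range.
#'
#' @inheritParams expected_stem_length
#' @param b Observed element-specific stem branch length (subs/site).
#' @return list(T_hat, clamped).
#' @export
invert_onset <- function(b, t0, t1, r, rho) {
  stopifnot(t1 < t0, r > 0, rho > 0, rho < 1)
  T_raw <- (r * t0 - rho * r * t1 - b) / (r * (1 - rho))
  T_hat <- min(max(T_raw, t1), t0)
  list(T_hat = T_hat, clamped = abs(T_raw - T_hat) > 1e-9)
}

#' Estimate when an element became conserved on a clade's stem branch
#'
#' Pipeline: (i) element-specific branch lengths from
#' [fit_branch_scales()]; (ii) the neutral per-Myr rate r from the
#' genome-wide neutral stem length divided by the stem duration; (iii) the
#' conserved scale rho from the ratio of element to neutral total ingroup
#' crown length; (iv) closed-form inversion of the expected stem length;
#' (v) standard error by nonparametric bootstrap over alignment columns.
#'
#' @param element An `msa` of the element (must include >= 1 outgroup to
#'   anchor the stem).
#' @param neutral_tree Neutral `phylo` with node ages attached
#'   ([set_node_ages()]); branch lengths are the genome-wide neutral
#'   lengths.
#' @param model Neutral `subst_model`.
#' @param ingroup Tip labels of the conserved clade.
#' @param n_boot Bootstrap replicates (default 200; warns below 20).
#' @param seed Integer seed for the bootstrap.
#' @return An `onset_estimate`: T_hat (Myr), se, ci (2.5/97.5 percentile),
#'   rho_hat, r, b_hat, t0, t1, clamped, frac_boot_clamped, n_boot, seed.
#' @export
estimate_onset <- function(element, neutral_tree, model, ingroup,
                           n_boot = 200L, seed = 1L) {
  ages <- node_ages(neutral_tree)
  if (is.null(ages)) stop("neutral tree has no node ages")
  if (n_boot < 20L) warning("n_boot < 20: standard error will be crude")
  mat <- if (inherits(element, "msa")) element$mat else element
  if (!length(setdiff(rownames(mat), ingroup)))
    stop("element alignment has no outgroup to anchor the stem")
  ctx <- peel_context(neutral_tree, mat)
  se_idx <- stem_edge(ctx$tr, ingroup)
  crown_idx <- setdiff(clade_edges(ctx$tr, ingroup, stem = TRUE), se_idx)
  t0 <- ages_for(ctx$tr, neutral_tree, ages)[ctx$tr$edge[se_idx, 1L]]
  t1 <- ages_for(ctx$tr, neutral_tree, ages)[ctx$tr$edge[se_idx, 2L]]
  neutral_lens <- ctx$tr$edge.length
  r <- neutral_lens[se_idx] / (t0 - t1)
  if (r <= 0) stop("neutral stem rate r <= 0")
  point <- onset_from_ctx(ctx, model, neutral_lens, se_idx, crown_idx,
                          t0, t1, r)
  boots <- with_rng(substream_seed(seed, "onset"), {
    w0 <- ctx$pat$weights
    ncols <- sum(w0)
    vapply(seq_len(n_boot), function(b) {
      wb <- as.numeric(stats::rmultinom(1L, ncols, w0 / ncols))
      ctx_b <- ctx
      ctx_b$pat$weights <- wb
      est <- onset_from_ctx(ctx_b, model, neutral_lens, se_idx, crown_idx,
                            t0, t1, r, error_ok = TRUE,
                            start = point$lens)  # warm start
      c(est$T_hat, est$clamped)
    }, c(0, 0))
  })
  T_boot <- boots[1L, ]
  ok <- !is.na(T_boot)
  structure(list(T_hat = point$T_hat, se = stats::sd(T_boot[ok]),
                 ci = unname(stats::quantile(T_boot[ok],
                                             c(0.025, 0.975))),
                 rho_hat = point$rho, r = r, b_hat = point$b,
                 t0 = t0, t1 = t1, clamped = point$clamped,
                 frac_boot_clamped = mean(boots[2L, ok]),
                 n_boot = n_boot, seed = seed),
            class = "onset_estimate")
}

# ages indexed by the postorder tree's node ids: node ids are preserved by
# ape::reorder (only the edge order changes), so ages carry over directly
ages_for <- function(tr_post, tree, ages) ages

onset_from_ctx <- function(ctx, model, neutral_lens, se_idx, crown_idx,
                           t0, t1, r, error_ok = FALSE, start = NULL) {
  if (is.null(start)) start <- pmax(neutral_lens, 1e-4)
  fit <- fit_lengths_ctx(ctx, model, start = start)
  b <- fit$lens[se_idx]
  rho <- sum(fit$lens[crown_idx]) / sum(neutral_lens[crown_idx])
  if (rho >= 1) {
    if (error_ok) return(list(T_hat = NA_real_, clamped = NA, b = b,
                              rho = rho, lens = fit$lens))
    stop("element not conserved in ingroup (rho >= 1)")
  }
  inv <- invert_onset(b, t0, t1, r, rho)
  list(T_hat = inv$T_hat, clamped = inv$clamped, b = b, rho = rho,
       lens = fit$lens)
}

#' Bootstrap standard error of the onset estimate
#'
#' Column-resampling bootstrap (the uncertainty machinery of
#' [estimate_onset()], exposed on its own). Deterministic given `seed`.
#'
#' @inheritParams estimate_onset
#' @return list(se, ci, frac_clamped).
#' @export
bootstrap_onset_se <- function(element, neutral_tree, model, ingroup,
                               n_boot = 200L, seed = 1L) {
  est <- estimate_onset(element, neutral_tree, model, ingroup,
                        n_boot = n_boot, seed = seed)
  list(se = est$se, ci = est$ci, frac_clamped = est$frac_boot_clamped)
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf(
    "Conservation onset: %.1f +/- %.1f Myr (95%% CI %.1f-%.1f); rho=%.3f, r=%.5f subs/site/Myr%s\n",
    x$T_hat, x$se, x$ci[1L], x$ci[2L], x$rho_hat, x$r,
    if (x$clamped) " [clamped]" else ""))
  cat(sprintf("  stem interval [%.1f, %.1f] Myr; %.0f%% of %d bootstrap replicates clamped\n",
              x$t1, x$t0, 100 * x$frac_boot_clamped, x$n_boot))
  invisible(x)
}

#' Write an onset estimate as a JSON report
#'
#' @param est An `onset_estimate`.
#' @param path Output file.
#' @export
write_onset_json <- function(est, path) {
  jsonlite::write_json(unclass(est), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
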