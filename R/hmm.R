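# Two-state phylogenetic HMM for conserved-element detection.
#
# State 1 ("conserved") emits alignment columns under the neutral tree with
# every branch scaled by rho < 1; state 2 ("nonconserved") emits under the
# unscaled neutral tree. Transitions: mu = P(conserved -> nonconserved),
# nu = P(nonconserved -> conserved); the stationary distribution is
# (nu, mu)/(mu + nu) and the expected conserved segment length is 1/mu.

#' Phylo-HMM parameters
#'
#' Defaults follow common conservation-scan tuning: expected element length
#' `1/mu = 45` columns and `nu` chosen so that the stationary conserved
#' coverage is 5%.
#'
#' @param rho Conserved-state branch scale in (0, 1].
#' @param mu Conserved-to-nonconserved transition probability in (0, 1).
#' @param nu Nonconserved-to-conserved transition probability in (0, 1);
#'   default gives 5% stationary conserved coverage.
#' @param coverage If `nu` is `NULL`, the stationary conserved fraction
#'   used to derive it.
#' @return An object of class `phylo_hmm_params`.
#' @export
phylo_hmm_params <- function(rho = 0.3, mu = 1 / 45, nu = NULL,
                             coverage = 0.05) {
  if (is.null(nu)) nu <- mu * coverage / (1 - coverage)
  stopifnot(rho > 0, rho <= 1, mu > 0, mu < 1, nu > 0, nu < 1)
  structure(list(rho = rho, mu = mu, nu = nu,
                 stationary = c(conserved = nu / (mu + nu),
                                nonconserved = mu / (mu + nu))),
            class = "phylo_hmm_params")
}

#' @export
print.phylo_hmm_params <- function(x, ...) {
  cat("Phylo-HMM: rho =", signif(x$rho, 4), ", mu =", signif(x$mu, 4),
      ", nu =", signif(x$nu, 4),
      sprintf("(coverage %.3f, expected length %.0f)\n",
              x$stationary[1L], 1 / x$mu))
  invisible(x)
}

#' Per-column emission log-likelihoods for both HMM states
#'
#' @param aln An `msa`.
#' @param model Neutral `subst_model`.
#' @param tree Neutral `phylo` tree.
#' @param rho Conserved branch scale in (0, 1].
#' @return Matrix with columns `conserved` and `nonconserved` (natural
#'   log), one row per alignment column. All-missing columns give (0, 0).
#' @export
emission_table <- function(aln, model, tree, rho) {
  stopifnot(rho > 0, rho <= 1)
  mat <- if (inherits(aln, "msa")) aln$mat else aln
  pat <- compress_patterns(encode_tips(mat, tree$tip.label))
  lc <- peel_coded_pat(tree, model, pat$tips, rho)
  ln <- peel_coded_pat(tree, model, pat$tips, 1)
  cbind(conserved = lc[pat$index], nonconserved = ln[pat$index])
}

peel_coded_pat <- function(tree, model, tips, scale) {
  tr <- ape::reorder.phylo(tree, "postorder")
  peel_loglik_cpp(tr$edge, edge_pmats(model, tr$edge.length * scale),
                  tips, model$pi, ape::Ntip(tr) + tr$Nnode,
                  ape::Ntip(tr) + 1L)
}

hmm_trans <- function(params) {
  matrix(c(1 - params$mu, params$mu,
           params$nu, 1 - params$nu), 2, 2, byrow = TRUE,
         dimnames = list(c("conserved", "nonconserved"),
                         c("conserved", "nonconserved")))
}

#' Forward-backward posterior decoding
#'
#' Scaled forward-backward recursions; numerically stable on 1e6-column
#' inputs.
#'
#' @param emissions Emission log-likelihood matrix from [emission_table()].
#' @param params A `phylo_hmm_params`.
#' @return list(posterior = per-column P(conserved), loglik = observed-data
#'   log-likelihood, xi = expected transition counts (2x2)).
#' @export
forward_backward <- function(emissions, params) {
  L <- nrow(emissions)
  if (is.null(L) || L == 0L) stop("empty emission table")
  A <- hmm_trans(params)
  init <- params$stationary
  # per-column emission likelihoods rescaled by their max (log-space shift)
  shift <- pmax(emissions[, 1L], emissions[, 2L])
  shift[!is.finite(shift)] <- 0
  B <- exp(emissions - shift)  # L x 2, values in [0,1]
  alpha <- matrix(0, L, 2)
  cvec <- numeric(L)
  a <- init * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  if (L == 1L) {
    g <- alpha[1L, ] / sum(alpha[1L, ])
    return(list(posterior = g[1L], loglik = log(cvec[1L]) + shift[1L],
                xi = matrix(0, 2, 2)))
  }
  for (t in 2:L) {
    a <- (alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, L, 2)
  beta[L, ] <- 1
  for (t in (L - 1L):1L) {
    b <- A %*% (B[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- b / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # expected transition counts (for Baum-Welch)
  xi <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    xi[i, j] <- sum(alpha[-L, i] * A[i, j] * B[-1L, j] * beta[-1L, j] /
                      cvec[-1L])
  }
  list(posterior = gamma[, 1L],
       loglik = sum(log(cvec)) + sum(shift),
       xi = xi)
}

viterbi_path <- function(emissions, params) {
  L <- nrow(emissions)
  logA <- log(hmm_trans(params))
  delta <- matrix(-Inf, L, 2)
  psi <- matrix(1L, L, 2)
  delta[1L, ] <- log(params$stationary) + emissions[1L, ]
  for (t in 2:L) {
    for (j in 1:2) {
      cand <- delta[t - 1L, ] + logA[, j]
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + emissions[t, j]
    }
  }
  path <- integer(L)
  path[L] <- which.max(delta[L, ])
  for (t in (L - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path  # 1 = conserved, 2 = nonconserved
}

#' Call conserved elements from HMM emissions
#'
#' Decodes the Viterbi state path (or thresholds the posterior when
#' `method = "posterior"`) and reports maximal conserved runs as
#' reference-genome intervals. Columns without a reference coordinate
#' cannot sit inside an element and split runs. Runs shorter than
#' `min_length` reference bases are discarded.
#'
#' @param emissions Emission matrix from [emission_table()].
#' @param params A `phylo_hmm_params`.
#' @param ref_pos Integer vector of 0-based reference coordinates per
#'   column (`NA` = unaligned to reference); defaults to consecutive.
#' @param chrom Reference chromosome for the output intervals.
#' @param min_length Minimum element length in bp (default 20).
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @param posterior_threshold Threshold for the posterior mode.
#' @return data.frame(chrom, start, end, name, score, mean_posterior):
#'   0-based half-open intervals, sorted, non-overlapping; `score` is the
#'   element log-odds in nats.
#' @export
viterbi_elements <- function(emissions, params, ref_pos = NULL,
                             chrom = "chr1", min_length = 20L,
                             method = c("viterbi", "posterior"),
                             posterior_threshold = 0.5) {
  method <- match.arg(method)
  L <- nrow(emissions)
  if (is.null(ref_pos)) ref_pos <- seq_len(L) - 1L
  fb <- forward_backward(emissions, params)
  state <- if (method == "viterbi") viterbi_path(emissions, params) else
    ifelse(fb$posterior >= posterior_threshold, 1L, 2L)
  ok <- state == 1L & !is.na(ref_pos)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_length)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    score = numeric(0), mean_posterior = numeric(0))
  for (k in seq_along(keep)) {
    i <- keep[k]
    cols <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      chrom = chrom,
      start = ref_pos[cols[1L]],
      end = ref_pos[cols[length(cols)]] + 1L,
      name = sprintf("ce%05d", k),
      score = sum(emissions[cols, 1L] - emissions[cols, 2L]),
      mean_posterior = mean(fb$posterior[cols])))
  }
  rownames(out) <- NULL
  out
}

#' Log-odds score of an element
#'
#' Sum over the element's columns of the conserved-vs-nonconserved emission
#' log-likelihood ratio (nats); additive over disjoint sub-intervals.
#'
#' @param cols Column indices of the element within the emission table.
#' @param emissions Emission matrix from [emission_table()].
#' @return Numeric score in nats.
#' @export
element_log_odds <- function(cols, emissions) {
  if (any(cols < 1L) || any(cols > nrow(emissions)))
    stop("element outside emission range")
  sum(emissions[cols, 1L] - emissions[cols, 2L])
}

#' Estimate the conserved-state scale and transition probabilities
#'
#' EM in the style of conservation-scan model training: Baum-Welch updates
#' for the transition probabilities and a golden-section maximisation of
#' the expected complete-data log-likelihood over `rho`. The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param aln An `msa` (>= 1000 columns recommended; warns below).
#' @param model Neutral `subst_model`.
#' @param tree Neutral `phylo` tree.
#' @param init Initial `phylo_hmm_params`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param fit_transitions Set `FALSE` to keep `mu`/`nu` fixed.
#' @return list(params, loglik_trace, converged, warning_flag).
#' @export
estimate_rho <- function(aln, model, tree, init = phylo_hmm_params(),
                         max_iter = 30L, tol = 1e-4,
                         fit_transitions = TRUE) {
  mat <- if (inherits(aln, "msa")) aln$mat else aln
  if (ncol(mat) < 1000L)
    warning("fewer than 1000 columns; rho estimate will be unstable")
  pat <- compress_patterns(encode_tips(mat, tree$tip.label))
  ln_pat <- peel_coded_pat(tree, model, pat$tips, 1)
  params <- init
  trace <- numeric(0)
  lc_pat <- peel_coded_pat(tree, model, pat$tips, params$rho)
  for (it in seq_len(max_iter)) {
    em <- cbind(lc_pat[pat$index], ln_pat[pat$index])
    fb <- forward_backward(em, params)
    trace <- c(trace, fb$loglik)
    if (it > 1L && trace[it] - trace[it - 1L] < tol) {
      return(list(params = params, loglik_trace = trace, converged = TRUE,
                  warning_flag = boundary_flag(params, fb)))
    }
    # M-step: transitions from expected counts
    if (fit_transitions) {
      mu <- fb$xi[1L, 2L] / sum(fb$xi[1L, ])
      nu <- fb$xi[2L, 1L] / sum(fb$xi[2L, ])
      mu <- min(max(mu, 1e-6), 1 - 1e-6)
      nu <- min(max(nu, 1e-6), 1 - 1e-6)
    } else {
      mu <- params$mu; nu <- params$nu
    }
    # M-step: rho by golden-section on expected complete-data loglik;
    # gamma aggregated per pattern so each evaluation is one peel
    gamma_pat <- rowsum(fb$posterior, pat$index)[, 1L]
    q_fun <- function(rho)
      -sum(gamma_pat * peel_coded_pat(tree, model, pat$tips, rho))
    opt <- stats::optimize(q_fun, lower = 1e-3, upper = 1, tol = 1e-4)
    rho_new <- opt$minimum
    lc_new <- peel_coded_pat(tree, model, pat$tips, rho_new)
    # guard: accept rho update only if observed loglik does not decrease
    fb_new <- forward_backward(cbind(lc_new[pat$index], ln_pat[pat$index]),
                               phylo_hmm_params(rho_new, mu, nu))
    if (fb_new$loglik >= fb$loglik - 1e-9) {
      params <- phylo_hmm_params(rho_new, mu, nu)
      lc_pat <- lc_new
    } else {
      params <- phylo_hmm_params(params$rho, mu, nu)
    }
  }
  em <- cbind(lc_pat[pat$index], ln_pat[pat$index])
  fb <- forward_backward(em, params)
  trace <- c(trace, fb$loglik)
  warning("EM did not converge after ", max_iter, " iterations")
  list(params = params, loglik_trace = trace, converged = FALSE,
       warning_flag = boundary_flag(params, fb))
}

# boundary diagnostics: rho indistinguishable from neutral, or the
# conserved state has (essentially) emptied out
boundary_flag <- function(params, fb) {
  params$rho > 0.95 || mean(fb$posterior) < 0.01
}
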