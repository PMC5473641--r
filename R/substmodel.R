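#' Reversible nucleotide substitution models
#'
#' Builds a time-reversible 4-state rate matrix Q from a model family,
#' equilibrium frequencies and exchangeability parameters. Q is normalised
#' so that the expected substitution rate at stationarity is 1, i.e. branch
#' lengths are in expected substitutions per site. This is the "neutral
#' (nonconserved) model" used by every likelihood in the package.
#'
#' Families:
#' * `JC69` — equal rates, frequencies forced to 1/4.
#' * `HKY85` — transition/transversion ratio `kappa`, free frequencies.
#' * `GTR` — six exchangeabilities `rates` in order AC, AG, AT, CG, CT, GT
#'   (GT conventionally 1), free frequencies.
#'
#' @param family One of `"JC69"`, `"HKY85"`, `"GTR"`.
#' @param pi Equilibrium frequencies (A, C, G, T); must be positive and is
#'   renormalised to sum to 1.
#' @param kappa Transition/transversion rate ratio (HKY85 only), > 0.
#' @param rates Six positive exchangeabilities (GTR only).
#' @return An object of class `subst_model` with elements `family`, `pi`,
#'   `Q`, the family parameters, and a cached eigendecomposition.
#' @examples
#' m <- substitution_model("HKY85", kappa = 3)
#' rowSums(m$Q)   # zeros
#' @export
substitution_model <- function(family = c("HKY85", "JC69", "GTR"),
                               pi = rep(0.25, 4), kappa = 2,
                               rates = NULL) {
  family <- match.arg(family)
  pi <- as.numeric(pi)
  stopifnot(length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  if (family == "JC69") pi <- rep(0.25, 4)
  s <- matrix(1, 4, 4)  # exchangeabilities, symmetric
  if (family == "HKY85") {
    stopifnot(is.numeric(kappa), kappa > 0)
    s[1, 3] <- s[3, 1] <- kappa  # A<->G
    s[2, 4] <- s[4, 2] <- kappa  # C<->T
  } else if (family == "GTR") {
    stopifnot(length(rates) == 6, all(rates > 0))
    s[1, 2] <- s[2, 1] <- rates[1]
    s[1, 3] <- s[3, 1] <- rates[2]
    s[1, 4] <- s[4, 1] <- rates[3]
    s[2, 3] <- s[3, 2] <- rates[4]
    s[2, 4] <- s[4, 2] <- rates[5]
    s[3, 4] <- s[4, 3] <- rates[6]
  }
  Q <- s * rep(pi, each = 4)  # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  norm <- -sum(pi * diag(Q))
  Q <- Q / norm
  dimnames(Q) <- list(DNA_BASES4, DNA_BASES4)
  # symmetric eigendecomposition via pi^(1/2) similarity (reversibility)
  d <- sqrt(pi)
  S <- Q * (d / rep(d, each = 4))  # diag(d) Q diag(1/d), symmetric
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  obj <- list(family = family, pi = pi, Q = Q,
              kappa = if (family == "HKY85") kappa else NULL,
              rates = if (family == "GTR") rates else NULL,
              eig = list(values = eig$values,
                         V = eig$vectors / d,        # diag(1/d) U
                         Vinv = t(eig$vectors) * rep(d, each = 4)))
  class(obj) <- "subst_model"
  obj
}

DNA_BASES4 <- c("A", "C", "G", "T")

#' @export
print.subst_model <- function(x, ...) {
  cat("Reversible substitution model:", x$family, "\n")
  cat("pi:", signif(x$pi, 4), "\n")
  if (!is.null(x$kappa)) cat("kappa:", signif(x$kappa, 4), "\n")
  if (!is.null(x$rates)) cat("rates:", signif(x$rates, 4), "\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A `subst_model`.
#' @param t Branch length in expected substitutions per site, `t >= 0`.
#' @return 4x4 row-stochastic matrix; rows are parent states.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single number >= 0")
  if (t == 0) {  # exact identity (eigen recomposition leaves ~1e-17 dust)
    P <- diag(4)
    dimnames(P) <- dimnames(model$Q)
    return(P)
  }
  e <- model$eig
  P <- e$V %*% (exp(e$values * t) * e$Vinv)
  P[P < 0] <- 0  # clamp eigen round-off
  dimnames(P) <- dimnames(model$Q)
  P
}

# stacked transition matrices for all edges: 4 x (4*nedge), column block e
# holds P(len[e]); this is the layout the C peeler consumes.
edge_pmats <- function(model, lens) {
  e <- model$eig
  nedge <- length(lens)
  out <- matrix(0, 4, 4 * nedge)
  V <- e$V; Vinv <- e$Vinv; lam <- e$values
  for (k in seq_len(nedge)) {
    P <- if (lens[k] == 0) diag(4) else {
      Pk <- V %*% (exp(lam * lens[k]) * Vinv)
      Pk[Pk < 0] <- 0
      Pk
    }
    out[, (4 * k - 3):(4 * k)] <- P
  }
  out
}

#' Serialize / read a substitution model as JSON
#'
#' @param model A `subst_model`.
#' @param path Output (input) file path.
#' @return `read_model_json` returns a `subst_model`.
#' @export
write_model_json <- function(model, path) {
  x <- list(family = model$family, pi = model$pi)
  if (!is.null(model$kappa)) x$kappa <- model$kappa
  if (!is.null(model$rates)) x$rates <- model$rates
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  substitution_model(x$family, pi = x$pi,
                     kappa = if (!is.null(x$kappa)) x$kappa else 2,
                     rates = x$rates)
}
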