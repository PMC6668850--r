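#' Study design for the two-species comparison
#'
#' @param species 0/1 (or two-level factor) per individual; 0 = assembly-A
#'   species, 1 = assembly-B species.
#' @param sex Optional 0/1 or two-level factor per individual.
#' @param batch Optional 0/1 or two-level factor per individual.
#' @return data.frame of class \code{study_design}.
#' @export
study_design <- function(species, sex = NULL, batch = NULL) {
  to01 <- function(z) {
    if (is.null(z)) return(NULL)
    if (is.factor(z) || is.character(z)) z <- as.integer(factor(z)) - 1L
    z <- as.numeric(z)
    if (!all(z %in% c(0, 1))) stop("design variables must be two-level")
    z
  }
  species <- to01(species)
  if (length(unique(species)) != 2) stop("need individuals from both species")
  d <- data.frame(species = species)
  if (!is.null(sex)) d$sex <- to01(sex)
  if (!is.null(batch)) d$batch <- to01(batch)
  class(d) <- c("study_design", "data.frame")
  d
}

# Shared vectorized OLS engine: fits Y (features x individuals) against a
# design matrix once, returning per-feature effect estimates and two-sided
# t-test p-values for `coef`. Covariates (other than `coef`) that make the
# design rank-deficient (e.g. perfectly confounded with species) are dropped
# with a warning. Features with zero variance get effect 0 and p = 1.
.ols_fit <- function(Y, design, coef = "species") {
  X <- stats::model.matrix(~ ., data = as.data.frame(design))
  keep <- colnames(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- setdiff(colnames(X), colnames(X)[qx$pivot[seq_len(qx$rank)]])
    if (coef %in% dep) stop("species term is confounded and cannot be estimated")
    warning("dropping confounded covariate(s): ", paste(dep, collapse = ", "))
    keep <- setdiff(keep, dep)
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n - p < 1) stop("need at least one residual degree of freedom")
  xtxi <- chol2inv(qr.R(qx))
  dimnames(xtxi) <- list(colnames(X), colnames(X))
  H <- xtxi %*% t(X)               # p x n
  B <- Y %*% t(H)                  # features x p
  colnames(B) <- colnames(X)
  resid <- Y - B %*% t(X)
  df <- n - p
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * xtxi[coef, coef])
  tt <- B[, coef] / se
  pv <- 2 * stats::pt(-abs(tt), df)
  flat <- .row_vars(Y) == 0
  if (any(flat)) {
    B[flat, ] <- 0
    B[flat, "(Intercept)"] <- rowMeans(Y)[flat]
    pv[flat] <- 1
    tt[flat] <- 0
  }
  pv[is.na(pv)] <- 1
  list(coefficients = B, sigma2 = sigma2, se = se, t = tt, p = pv,
       df = df, dropped = setdiff(colnames(stats::model.matrix(~ ., as.data.frame(design))), keep))
}

#' Fit the per-contact linear model of species, sex and batch effects
#'
#' For each contact, models the individual log2 normalized frequencies as
#' an intercept plus fixed species, sex and batch effects, by ordinary least
#' squares, and tests the species effect with a two-sided t-test. Contacts
#' with zero variance across individuals get effect 0 and p = 1 by
#' convention. Covariates perfectly confounded with species are dropped
#' with a warning.
#'
#' @param Y Numeric matrix (contacts x individuals) of log2 frequencies, or
#'   a single numeric vector for one contact.
#' @param design A \code{\link{study_design}}.
#' @return data.frame with columns \code{beta0}, \code{beta_sp}, and (when
#'   present in the design) \code{beta_sx}, \code{beta_btc}, plus
#'   \code{sigma2}, \code{t}, \code{p}, \code{df}.
#' @export
fit_contact_model <- function(Y, design) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  stopifnot(ncol(Y) == nrow(design))
  if (nrow(design) < 5) stop("need at least 5 individuals")
  fit <- .ols_fit(Y, design, coef = "species")
  out <- data.frame(beta0 = fit$coefficients[, "(Intercept)"],
                    beta_sp = fit$coefficients[, "species"])
  if ("sex" %in% colnames(fit$coefficients)) out$beta_sx <- fit$coefficients[, "sex"]
  if ("batch" %in% colnames(fit$coefficients)) out$beta_btc <- fit$coefficients[, "batch"]
  out$sigma2 <- fit$sigma2
  out$t <- fit$t
  out$p <- fit$p
  out$df <- fit$df
  rownames(out) <- rownames(Y)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Remove contacts whose mate-pair distance differs across assemblies
#'
#' Contacts whose anchor-to-anchor genomic distance differs by strictly more
#' than \code{max_diff} between the two assemblies are removed (a large
#' difference inflates apparent inter-species contact differences because
#' read support decays with distance).
#'
#' @param table data.frame with columns \code{dist_a} and \code{dist_b}.
#' @param max_diff Maximum tolerated absolute difference in base pairs
#'   (default 20000); equality is retained.
#' @return list with \code{kept} and \code{removed} data.frames.
#' @export
matepair_distance_filter <- function(table, max_diff = 20000) {
  stopifnot(all(c("dist_a", "dist_b") %in% names(table)))
  drop <- abs(table$dist_a - table$dist_b) > max_diff
  list(kept = table[!drop, , drop = FALSE],
       removed = table[drop, , drop = FALSE])
}

#' Per-chromosome binomial test of directional asymmetry
#'
#' For significant differential contacts, tests per chromosome whether the
#' split between contacts stronger in each species is consistent with an
#' even 50/50 null, using an exact two-sided binomial test. A genome-wide
#' row is included.
#'
#' @param chrom Chromosome label per significant contact.
#' @param beta_sp Species effect estimate per significant contact; positive
#'   values mean a higher frequency in the species coded 1.
#' @return data.frame with per-chromosome counts, the percentage higher in
#'   the species coded 1, and the binomial p-value (NA for empty
#'   chromosomes).
#' @export
chromosome_asymmetry_test <- function(chrom, beta_sp) {
  stopifnot(length(chrom) == length(beta_sp))
  one <- function(b) {
    n1 <- sum(b > 0)
    n <- length(b)
    p <- if (n > 0) stats::binom.test(n1, n, 0.5)$p.value else NA_real_
    data.frame(n_higher_sp1 = n1, n_higher_sp0 = n - n1,
               pct_higher_sp1 = if (n > 0) 100 * n1 / n else NA_real_,
               p = p)
  }
  groups <- split(beta_sp, chrom)
  res <- do.call(rbind, lapply(groups, one))
  res <- cbind(chrom = names(groups), res)
  res <- rbind(res, cbind(chrom = "genome", one(beta_sp)))
  rownames(res) <- NULL
  res
}
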