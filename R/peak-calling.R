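#' Conditional binomial test for bin-level enrichment
#'
#' Under independence of ChIP count X and input count Y in an unbound bin,
#' X given X + Y is binomial with proportion p0.  p0 is estimated from the
#' background-dominated bins: the ratio of total ChIP to total (ChIP +
#' input) tags across bins whose total count is at most
#' \code{lowCountThreshold}.  The per-bin p-value is the upper binomial tail
#' P(Binom(X + Y, p0) >= X).
#'
#' @param bins a \code{\linkS4class{BinTable}}.
#' @param lowCountThreshold bins with X + Y at or below this contribute to
#'   the p0 estimate (default 1).
#' @return object of class \code{"CBTestResult"}: list with \code{pvalues},
#'   \code{p0} and \code{low_count_threshold}.  When no low-count bins
#'   exist (or they give a degenerate p0), the global depth ratio is used
#'   with a warning.
#' @export
cbTest <- function(bins, lowCountThreshold = 1L) {
    stopifnot(is(bins, "BinTable"))
    mc <- S4Vectors::mcols(bins@bins)
    X <- mc$chip_count
    Y <- mc$input_count
    low <- (X + Y) <= lowCountThreshold
    num <- sum(X[low]); den <- sum(X[low]) + sum(Y[low])
    p0 <- if (den > 0) num / den else NA_real_
    if (is.na(p0) || p0 <= 0 || p0 >= 1) {
        warning("no informative low-count bins; falling back to the global ",
                "depth ratio for p0")
        p0 <- sum(X) / (sum(X) + sum(Y))
    }
    p <- pbinom(X - 1L, X + Y, p0, lower.tail = FALSE)
    structure(list(pvalues = p, p0 = p0,
                   low_count_threshold = as.integer(lowCountThreshold)),
              class = "CBTestResult")
}

.modelMatrix <- function(mc, knots) {
    gcb <- splines::bs(mc$gc, degree = 1L, knots = knots,
                       Boundary.knots = range(mc$gc, 0, 1))
    cbind(intercept = 1, mappability = mc$mappability,
          gc1 = gcb[, 1L], gc2 = gcb[, 2L], gc3 = gcb[, 3L],
          log_input = log1p(mc$input_count))
}

#' Fit a two-component negative-binomial mixture to bin counts
#'
#' Background (unbound) bins follow a negative binomial whose log-mean is
#' linear in mappability, a piecewise-linear B-spline in GC content (knots
#' at the GC 1st and 3rd quartiles) and log(1 + input count).  Bound bins
#' follow the same background plus a shift constant (the minimum count
#' observable in a bound region) and a mixture of two negative binomials.
#' Fitting alternates a weighted negative-binomial regression on the bins
#' currently attributed to background with an update of the mixture
#' responsibilities (EM); the background dispersion is re-estimated by
#' method of moments each iteration.  The fit is deterministic: the
#' initialization uses the trimmed data, and signal components start at 5x
#' and 20x the mean background level.
#'
#' @param bins a \code{\linkS4class{BinTable}} (at least ~1,000 bins
#'   recommended so the GC quartile knots are stable).
#' @param shift minimum bound-region count (default 3).
#' @param maxIter maximum EM iterations (default 25).
#' @param tol convergence tolerance on coefficient and mixing-proportion
#'   changes (default 1e-4).
#' @return an \code{\linkS4class{NBMixtureFit}}; non-convergence within
#'   \code{maxIter} returns the best fit with a warning.
#' @export
fitNBMixture <- function(bins, shift = 3L, maxIter = 25L, tol = 1e-4) {
    stopifnot(is(bins, "BinTable"))
    mc <- S4Vectors::mcols(bins@bins)
    X <- mc$chip_count
    n <- length(X)
    if (n < 100L) stop("too few bins to fit the mixture model")
    knots <- unname(quantile(mc$gc, c(0.25, 0.75), na.rm = TRUE))
    mmx <- .modelMatrix(mc, knots)

    # initialization: background regression on the lower 99% of counts
    init_sel <- X <= quantile(X, 0.99)
    fit <- glm.fit(mmx[init_sel, , drop = FALSE], X[init_sel],
                   family = stats::poisson())
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    mu <- drop(exp(mmx %*% beta))
    theta <- tryCatch(MASS::theta.mm(X[init_sel], mu[init_sel],
                                     dfr = sum(init_sel) - ncol(mmx)),
                      error = function(e) 1)
    theta <- max(min(theta, 1e4), 1e-3)
    m0 <- mean(mu)
    sig <- list(mu = c(5 * m0, 20 * m0), size = c(2, 2), prop = c(0.5, 0.5))
    pi1 <- 0.02
    Xs <- X - shift
    ok_sig <- Xs >= 0L & X > 0L

    post <- numeric(n)
    converged <- FALSE
    it <- 0L
    repeat {
        it <- it + 1L
        # E step
        f_bg <- dnbinom(X, size = theta, mu = mu)
        f1 <- ifelse(ok_sig, dnbinom(pmax(Xs, 0L), size = sig$size[1L],
                                     mu = sig$mu[1L]), 0)
        f2 <- ifelse(ok_sig, dnbinom(pmax(Xs, 0L), size = sig$size[2L],
                                     mu = sig$mu[2L]), 0)
        f_sig <- sig$prop[1L] * f1 + sig$prop[2L] * f2
        den <- pi1 * f_sig + (1 - pi1) * f_bg
        post <- ifelse(den > 0, pi1 * f_sig / den, 0)
        # M step
        pi_new <- min(max(mean(post), 1e-6), 0.5)
        wbg <- 1 - post
        fit <- suppressWarnings(glm.fit(mmx, X, weights = wbg,
            family = MASS::negative.binomial(theta), start = beta))
        beta_new <- fit$coefficients
        beta_new[is.na(beta_new)] <- 0
        mu <- drop(exp(mmx %*% beta_new))
        theta <- tryCatch(
            max(min(MASS::theta.mm(X, mu, dfr = sum(wbg) - ncol(mmx),
                                   weights = wbg), 1e4), 1e-3),
            error = function(e) theta)
        # signal components from posterior-weighted shifted counts
        if (sum(post[ok_sig]) > 1e-8) {
            r1den <- sig$prop[1L] * f1 + sig$prop[2L] * f2
            r1 <- ifelse(r1den > 0, sig$prop[1L] * f1 / r1den, 0.5)
            w1 <- post * r1; w2 <- post * (1 - r1)
            upd <- function(wt) {
                s <- sum(wt[ok_sig])
                if (s < 1e-8) return(NULL)
                m <- sum(wt[ok_sig] * Xs[ok_sig]) / s
                v <- sum(wt[ok_sig] * (Xs[ok_sig] - m)^2) / s
                size <- if (v > m) m^2 / (v - m) else 1e4
                list(mu = max(m, 1e-3), size = max(min(size, 1e4), 1e-3),
                     w = s)
            }
            u1 <- upd(w1); u2 <- upd(w2)
            if (!is.null(u1) && !is.null(u2)) {
                q <- u1$w / (u1$w + u2$w)
                sig <- list(mu = c(u1$mu, u2$mu),
                            size = c(u1$size, u2$size),
                            prop = c(min(max(q, 0.05), 0.95),
                                     1 - min(max(q, 0.05), 0.95)))
            }
        }
        delta <- max(abs(beta_new - beta), abs(pi_new - pi1))
        beta <- beta_new
        pi1 <- pi_new
        if (delta < tol) { converged <- TRUE; break }
        if (it >= maxIter) break
    }
    if (!converged)
        warning("EM did not converge within ", maxIter, " iterations")
    # final posterior with the converged parameters
    f_bg <- dnbinom(X, size = theta, mu = mu)
    f1 <- ifelse(ok_sig, dnbinom(pmax(Xs, 0L), size = sig$size[1L],
                                 mu = sig$mu[1L]), 0)
    f2 <- ifelse(ok_sig, dnbinom(pmax(Xs, 0L), size = sig$size[2L],
                                 mu = sig$mu[2L]), 0)
    f_sig <- sig$prop[1L] * f1 + sig$prop[2L] * f2
    den <- pi1 * f_sig + (1 - pi1) * f_bg
    post <- ifelse(den > 0, pi1 * f_sig / den, 0)
    post[X == 0L] <- 0   # empty bins are never bound
    names(beta) <- colnames(mmx)
    new("NBMixtureFit", coefficients = beta, theta = theta, mixprop = pi1,
        signal = c(sig, list(shift = as.integer(shift))), posterior = post,
        gcKnots = knots, converged = converged, iterations = it)
}

#' Call peaks from bin-level scores
#'
#' For conditional-binomial results, Benjamini-Hochberg is applied to the
#' per-bin p-values at the requested FDR level.  For mixture fits, direct
#' posterior-probability FDR control is used: bins are ranked by posterior
#' probability of binding and the largest declared set whose mean
#' background posterior (1 - binding posterior) is at most the level is
#' taken.  Bound bins with fewer than \code{minChipCount} ChIP tags are then
#' discarded, and remaining contiguous bound bins are merged into peaks.
#'
#' @param scores a \code{"CBTestResult"} (from \code{\link{cbTest}}) or an
#'   \code{\linkS4class{NBMixtureFit}}.
#' @param bins the \code{BinTable} the scores were computed from.
#' @param fdr FDR level (default 0.05).
#' @param minChipCount minimum ChIP tag count for a bound bin (default 30).
#' @return \code{GRanges} of peaks with metadata columns \code{score}
#'   (minimum p-value or maximum binding posterior over member bins),
#'   \code{summit} (start of the member bin with the largest fractional
#'   ChIP count), \code{chip_sum}, \code{input_sum},
#'   \code{avg_log2_enrichment} (mean over member bins of log2 ChIP/input
#'   after scaling both samples to the same total depth, with a 0.5
#'   pseudocount), \code{mappability}, \code{gc} and \code{n_bins}.
#' @export
callPeaks <- function(scores, bins, fdr = 0.05, minChipCount = 30L) {
    stopifnot(is(bins, "BinTable"), fdr > 0, fdr < 1)
    mc <- S4Vectors::mcols(bins@bins)
    n <- length(bins@bins)
    if (n == 0L) return(.emptyPeaks())
    if (inherits(scores, "CBTestResult")) {
        p <- scores$pvalues
        stopifnot(length(p) == n)
        bound <- p.adjust(p, method = "BH") <= fdr
        binscore <- p
        better <- function(a, b) pmin(a, b)
        pick <- min
    } else if (is(scores, "NBMixtureFit")) {
        post <- posteriorProb(scores)
        stopifnot(length(post) == n)
        ord <- order(post, decreasing = TRUE)
        bgp <- 1 - post[ord]
        ok <- cumsum(bgp) / seq_len(n) <= fdr
        ndecl <- if (any(ok)) max(which(ok)) else 0L
        bound <- logical(n)
        if (ndecl > 0L) bound[ord[seq_len(ndecl)]] <- TRUE
        binscore <- post
        pick <- max
    } else stop("scores must be a CBTestResult or an NBMixtureFit")
    bound <- bound & mc$chip_count >= minChipCount
    if (!any(bound)) return(.emptyPeaks())
    bb <- bins@bins[bound]
    peaks <- GenomicRanges::reduce(bb, min.gapwidth = 1L)
    hit <- GenomicRanges::findOverlaps(peaks, bb)
    qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
    mcb <- S4Vectors::mcols(bb)
    sc_tot <- sum(mc$chip_count)
    in_tot <- sum(mc$input_count)
    ratio <- if (in_tot > 0) sc_tot / in_tot else 1
    l2e <- log2((mcb$chip_count + 0.5) / (mcb$input_count * ratio + 0.5))
    sb <- binscore[bound]
    agg <- function(v, f) unname(vapply(split(v, qi), f, 0))
    summit <- unname(vapply(split(si, qi), function(i)
        GenomicRanges::start(bb)[i[which.max(mcb$chip_fractional[i])]], 0))
    S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
        score = agg(sb[si], pick),
        summit = as.integer(summit),
        chip_sum = agg(mcb$chip_count[si], sum),
        input_sum = agg(mcb$input_count[si], sum),
        avg_log2_enrichment = agg(l2e[si], mean),
        mappability = agg(mcb$mappability[si], mean),
        gc = agg(mcb$gc[si], mean),
        n_bins = agg(rep(1, length(si)), sum))
    peaks
}

.emptyPeaks <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        score = numeric(), summit = integer(), chip_sum = numeric(),
        input_sum = numeric(), avg_log2_enrichment = numeric(),
        mappability = numeric(), gc = numeric(), n_bins = numeric())
    gr
}

#' Observed vs fitted count-frequency table
#'
#' Goodness-of-fit summary for a mixture fit: for every ChIP count value
#' from 0 to the maximum observed, the observed bin frequency and the
#' model-expected frequency (background and signal components mixed at the
#' fitted proportion, summed over bins because the background mean varies
#' with the covariates).
#'
#' @param fit an \code{NBMixtureFit}.
#' @param bins the fitted \code{BinTable}.
#' @return data.frame with columns \code{count}, \code{observed},
#'   \code{expected}.
#' @export
gofSummary <- function(fit, bins) {
    stopifnot(is(fit, "NBMixtureFit"), is(bins, "BinTable"))
    mc <- S4Vectors::mcols(bins@bins)
    X <- mc$chip_count
    knots <- fit@gcKnots
    mmx <- .modelMatrix(mc, knots)
    mu <- drop(exp(mmx %*% fit@coefficients))
    cmax <- max(X)
    counts <- 0:cmax
    shift <- fit@signal$shift
    expected <- vapply(counts, function(cc) {
        e_bg <- sum(dnbinom(cc, size = fit@theta, mu = mu))
        cs <- cc - shift
        e_sig <- if (cs >= 0)
            length(mu) * (fit@signal$prop[1L] *
                              dnbinom(cs, size = fit@signal$size[1L],
                                      mu = fit@signal$mu[1L]) +
                          fit@signal$prop[2L] *
                              dnbinom(cs, size = fit@signal$size[2L],
                                      mu = fit@signal$mu[2L]))
        else 0
        (1 - fit@mixprop) * e_bg + fit@mixprop * e_sig
    }, 0)
    observed <- tabulate(X + 1L, nbins = cmax + 1L)
    data.frame(count = counts, observed = observed, expected = expected)
}
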