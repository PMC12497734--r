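#' Normalize firing rates to baseline
#'
#' @param mfr mean firing rate(s) under the condition(s), spikes/s.
#' @param baseline baseline mean firing rate, spikes/s (> 0).
#' @return unitless response(s): `mfr / baseline` (baseline maps to 1).
#' @export
normalizeToBaseline <- function(mfr, baseline) {
    if (length(baseline) != 1L || !is.finite(baseline) || baseline <= 0)
        stop("baseline MFR must be a single positive number")
    mfr / baseline
}

.hillCurve <- function(c_, ic50, n, top, bottom) {
    bottom + (top - bottom) / (1 + (c_ / ic50)^n)
}

#' Fit the Hill equation to a dose-response series
#'
#' Least-squares fit of the inhibition curve
#' `r(c) = bottom + (top - bottom) / (1 + (c / IC50)^n)`
#' with asymptotes fixed at `top = 1`, `bottom = 0` by default (responses
#' are baseline-normalized and full block is assumed at saturation; set
#' `free_asymptotes = TRUE` to fit them). The fit is performed on
#' log10-concentration with a multi-start over an IC50 grid (one start per
#' decade spanning the data), avoiding local minima across the typical
#' 4-decade ladder. Data in which the IC50 is unidentifiable — flat or
#' non-monotone response with too little dynamic range, or an optimum pinned
#' far outside the sampled range — are reported with `converged = FALSE`
#' rather than a silent success.
#'
#' @param concentrations molar concentrations (>= 4 points spanning >= 2
#'   decades).
#' @param responses normalized responses (unitless, expected in `[0, ~1.2]`).
#' @param fixed_top,fixed_bottom asymptote values when not free.
#' @param free_asymptotes fit `top` and `bottom` as parameters.
#' @return a [DoseResponseFit-class].
#' @seealso [simulateDoseResponse()]
#' @export
#' @examples
#' d <- simulateDoseResponse(ic50 = 2e-9, hill_n = 1)
#' fitHill(d$concentration, d$response)
fitHill <- function(concentrations, responses, fixed_top = 1,
                    fixed_bottom = 0, free_asymptotes = FALSE) {
    ord <- order(concentrations)
    cc <- concentrations[ord]; rr <- responses[ord]
    if (length(cc) < 4L)
        stop("need at least 4 concentration points")
    if (log10(max(cc) / min(cc)) < 2)
        stop("concentrations must span at least 2 decades")
    if (any(cc <= 0)) stop("concentrations must be positive")
    x <- log10(cc)
    fail <- new("DoseResponseFit", concentrations = cc,
                responses = pmax(rr, 0), ic50 = NA_real_, hillN = NA_real_,
                top = fixed_top, bottom = fixed_bottom,
                residualNorm = NA_real_, converged = FALSE)
    if (diff(range(rr)) < 0.2) return(fail)   # flat: IC50 unidentifiable
    starts <- seq(floor(min(x)), ceiling(max(x)), by = 1)
    best <- NULL
    for (m0 in starts) {
        fit <- if (free_asymptotes) {
            try(minpack.lm::nlsLM(
                rr ~ bot + (top - bot) / (1 + 10^(n * (x - m))),
                start = list(m = m0, n = 1, top = max(rr), bot = min(rr)),
                lower = c(m = min(x) - 3, n = 1e-3, top = -Inf, bot = -Inf),
                upper = c(m = max(x) + 3, n = 100, top = Inf, bot = Inf),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
                silent = TRUE)
        } else {
            bot <- fixed_bottom; top <- fixed_top
            try(minpack.lm::nlsLM(
                rr ~ bot + (top - bot) / (1 + 10^(n * (x - m))),
                start = list(m = m0, n = 1),
                lower = c(m = min(x) - 3, n = 1e-3),
                upper = c(m = max(x) + 3, n = 100),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
                silent = TRUE)
        }
        if (inherits(fit, "try-error")) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
    }
    if (is.null(best)) return(fail)
    cf <- stats::coef(best$fit)
    ic50 <- 10^cf[["m"]]
    top <- if (free_asymptotes) cf[["top"]] else fixed_top
    bottom <- if (free_asymptotes) cf[["bot"]] else fixed_bottom
    # identifiability guard: IC50 must be resolvable within ~a decade of the
    # sampled range and the curve must actually descend over the data
    ok <- ic50 >= min(cc) / 10 && ic50 <= max(cc) * 10 && cf[["n"]] > 0
    if (!ok) return(fail)
    new("DoseResponseFit", concentrations = cc, responses = pmax(rr, 0),
        ic50 = ic50, hillN = cf[["n"]], top = top, bottom = bottom,
        residualNorm = sqrt(best$rss), converged = TRUE)
}

#' Sample a fitted Hill curve
#'
#' @param fit a converged [DoseResponseFit-class].
#' @param points_per_decade sampling density (default 50).
#' @return data.frame `concentration`, `response`.
#' @export
hillCurve <- function(fit, points_per_decade = 50) {
    stopifnot(fit@converged)
    x <- seq(log10(min(fit@concentrations)), log10(max(fit@concentrations)),
             length.out = points_per_decade *
                 ceiling(log10(max(fit@concentrations) /
                               min(fit@concentrations))))
    data.frame(concentration = 10^x,
               response = .hillCurve(10^x, fit@ic50, fit@hillN, fit@top,
                                     fit@bottom))
}
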