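.MU_EPS <- 1e-9

#' Expected count of a component function
#'
#' Evaluates one component of a candidate model. With the default log link a
#' constant component gives mu = offset * exp(c) and a linear component
#' mu = offset * exp(a + b * log10_area); with the identity link the linear
#' predictor is used directly, floored at a small epsilon to keep the count
#' mean positive. The offset (1 for abundance; 2 for the two-year richness
#' response) multiplies the mean.
#'
#' @param component "constant" or "linear" (a component descriptor from a
#'   \linkS4class{CandidateModel} also works)
#' @param params numeric: \code{c} for constant; \code{c(a, b)} for linear
#' @param log10_area numeric vector (ignored by constant components)
#' @param offset 1 or 2
#' @param link "log" (default) or "identity"
#' @return numeric vector of expected counts
#' @examples
#' meanFunction("constant", log(5))              # 5
#' meanFunction("linear", c(0, 1), log10_area = 2)  # exp(2)
#' @export
meanFunction <- function(component, params, log10_area = 0, offset = 1,
                         link = c("log", "identity")) {
  link <- match.arg(link)
  if (is.list(component)) component <- component$form
  if (!offset %in% c(1, 2)) stop("offset must be 1 or 2")
  eta <- switch(component,
    constant = rep(params[1], length.out = max(1L, length(log10_area))),
    linear = params[1] + params[2] * log10_area,
    stop("component form must be 'constant' or 'linear'"))
  mu <- if (link == "log") offset * exp(eta) else
    offset * pmax(eta, .MU_EPS)
  if (any(!is.finite(mu)))
    stop("non-finite expected count: optimizer divergence")
  mu
}

#' Poisson negative log-likelihood
#'
#' Sum over observations of mu - y*log(mu) + log(y!).
#'
#' @param counts non-negative integer counts
#' @param mus positive means, same length
#' @return total negative log-likelihood (0 for empty input)
#' @export
nllPoisson <- function(counts, mus) {
  if (length(counts) != length(mus)) stop("length mismatch")
  if (!length(counts)) return(0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(mus <= 0)) stop("Poisson mean must be positive")
  sum(mus - counts * log(mus) + lgamma(counts + 1))
}

#' Negative Binomial negative log-likelihood (mean-dispersion form)
#'
#' Uses the mu/k parameterization with variance mu + mu^2/k; the Poisson
#' likelihood is the k -> Inf limit. Written with log1p so that very large k
#' reproduces the Poisson value to high accuracy.
#'
#' @param counts non-negative integer counts
#' @param mus positive means
#' @param k positive dispersion
#' @return total negative log-likelihood (0 for empty input)
#' @export
nllNegbin <- function(counts, mus, k) {
  if (length(counts) != length(mus)) stop("length mismatch")
  if (k <= 0) stop("dispersion k must be positive")
  if (!length(counts)) return(0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(mus <= 0)) stop("mean must be positive")
  ## counts are integers, so lgamma(y + k) - lgamma(k) = sum_j log(k + j),
  ## j = 0..y-1 — exact, and free of the catastrophic cancellation the
  ## lgamma difference suffers at large k (the Poisson boundary)
  lgr <- vapply(counts, function(y)
    if (y == 0) 0 else sum(log(k + seq_len(y) - 1)), numeric(1))
  ll <- lgr - lgamma(counts + 1) -
    k * log1p(mus / k) + counts * (log(mus) - log(k + mus))
  -sum(ll)
}

## mean vector of a whole model from its design matrix
.muFromDesign <- function(X, beta, offset, link) {
  eta <- drop(X %*% beta)
  if (link == "log") offset * exp(eta) else offset * pmax(eta, .MU_EPS)
}

.responseVector <- function(model, responses) {
  if (model@response == "abundance")
    list(y = responses$abundance, offset = rep(1, nrow(responses)))
  else
    list(y = responses$richness_response, offset = as.numeric(responses$offset))
}

#' Whole-model negative log-likelihood
#'
#' The model NLL is the sum over component functions of their per-site
#' negative log-likelihoods — equivalently the NLL of the stacked mean vector
#' built from the model's design matrix, under the model's distribution
#' (one dispersion shared across components when Negative Binomial).
#'
#' @param model a \linkS4class{CandidateModel}
#' @param params numeric of length \code{paramCount(model)}; coefficients on
#'   the link scale, log-dispersion last when negbin
#' @param responses data.frame from \code{\link{aggregateResponses}} (every
#'   site must belong to a landscape covered by the model)
#' @param link "log" or "identity"
#' @return scalar negative log-likelihood
#' @export
modelNLL <- function(model, params, responses, link = c("log", "identity")) {
  link <- match.arg(link)
  if (length(params) != model@K)
    stop("expected ", model@K, " parameters, got ", length(params))
  X <- designMatrix(model, responses)
  rv <- .responseVector(model, responses)
  nb <- model@distribution == "negbin"
  beta <- if (nb) params[-length(params)] else params
  mu <- .muFromDesign(X, beta, rv$offset, link)
  if (any(!is.finite(mu)))
    stop("non-finite expected count: optimizer divergence")
  if (nb) nllNegbin(rv$y, mu, exp(params[length(params)]))
  else nllPoisson(rv$y, mu)
}

## moment-based starting values: per-column means and per-component
## least-squares slopes on log((y + 0.5) / offset)
.momentStart <- function(model, responses, link) {
  X <- designMatrix(model, responses)
  cols <- .designColumns(model@components)
  rv <- .responseVector(model, responses)
  z <- if (link == "log") log((rv$y + 0.5) / rv$offset) else rv$y / rv$offset
  start <- numeric(length(cols))
  slope_cols <- vapply(cols, function(cc) cc$kind == "slope", logical(1))
  for (j in which(slope_cols)) {
    member <- responses$landscape_id %in% cols[[j]]$landscapes
    x <- responses$log10_area[member]
    start[j] <- if (length(unique(x)) > 1)
      stats::cov(x, z[member]) / stats::var(x) else 0
  }
  for (j in which(!slope_cols)) {
    member <- responses$landscape_id %in% cols[[j]]$landscapes
    b <- 0
    for (js in which(slope_cols))
      if (any(responses$landscape_id[member] %in% cols[[js]]$landscapes))
        b <- start[js]
    start[j] <- mean(z[member] - b * responses$log10_area[member] *
                       (b != 0))
  }
  if (model@distribution == "negbin") {
    m <- mean(rv$y / rv$offset)
    v <- stats::var(rv$y / rv$offset)
    k0 <- if (!is.na(v) && v > m) m^2 / (v - m) else 10
    start <- c(start, log(max(k0, 1e-3)))
  }
  stats::setNames(start, paramNames(model))
}

## deterministic multi-start pattern: the moment start plus +/- 0.5 block
## perturbations (keeps fitting off the RNG stream)
.startSet <- function(start0, model, n_starts) {
  nm <- paramNames(model)
  is_slope <- grepl("^slope\\[", nm) | nm == "log_k"
  if (!any(is_slope)) is_slope <- rep(TRUE, length(nm))
  deltas <- list(0 * start0,
                 ifelse(!is_slope, 0.5, 0),
                 ifelse(!is_slope, -0.5, 0),
                 ifelse(is_slope, 0.5, 0),
                 ifelse(is_slope, -0.5, 0),
                 rep(0.5, length(nm)), rep(-0.5, length(nm)))
  lapply(deltas[seq_len(min(n_starts, length(deltas)))],
         function(d) start0 + d)
}

#' Maximum-likelihood fit of a candidate model
#'
#' Minimizes the whole-model negative log-likelihood by derivative-free
#' simplex optimization (Nelder-Mead; golden-section for one-parameter
#' models) from a moment-based starting point plus deterministic
#' perturbations of it, keeping the best converged solution. The dispersion
#' of Negative Binomial models is optimized on the log scale.
#'
#' @param model a \linkS4class{CandidateModel}
#' @param responses data.frame from \code{\link{aggregateResponses}}
#' @param link "log" (default) or "identity"
#' @param n_starts number of starting points (default 5)
#' @param maxit,reltol optimizer control (defaults 2000, 1e-8)
#' @param distribution optional override of the model's distribution policy
#'   (e.g. force "poisson" for a constant abundance model)
#' @return a \linkS4class{FittedModel}; \code{converged} is FALSE when no
#'   start converged (such fits are excluded from selection tables)
#' @export
fitModel <- function(model, responses, link = c("log", "identity"),
                     n_starts = 5L, maxit = 2000L, reltol = 1e-8,
                     distribution = NULL) {
  link <- match.arg(link)
  if (!is.null(distribution) && distribution != model@distribution) {
    comps <- model@components
    K <- length(.designColumns(comps)) + (distribution == "negbin")
    model <- new("CandidateModel", model_id = model@model_id,
                 response = model@response, components = comps,
                 distribution = distribution, K = as.integer(K),
                 landscapes = model@landscapes)
  }
  for (cc in model@components) {
    member <- responses$landscape_id %in% cc$landscapes
    if (!any(member))
      stop("component on {", paste(cc$landscapes, collapse = ","),
           "} has no sites")
    if (cc$form == "linear" &&
        length(unique(responses$log10_area[member])) < 2)
      stop("linear component on {", paste(cc$landscapes, collapse = ","),
           "} needs >= 2 distinct patch areas")
  }
  nb <- model@distribution == "negbin"
  obj <- function(p) {
    ## beyond k = e^25 the NB is numerically Poisson: clamp so the boundary
    ## region is flat and the simplex can converge there
    if (nb) p[length(p)] <- min(p[length(p)], 25)
    v <- tryCatch(modelNLL(model, p, responses, link), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  start0 <- .momentStart(model, responses, link)
  best <- NULL
  for (s in .startSet(start0, model, n_starts)) {
    if (length(s) == 1L) {
      o <- stats::optimize(function(p) obj(c(p)), lower = s - 12, upper = s + 12,
                           tol = 1e-10)
      cand <- list(par = stats::setNames(o$minimum, names(start0)),
                   value = o$objective, converged = TRUE)
    } else {
      o <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
      cand <- list(par = o$par, value = o$value, converged = o$convergence == 0)
    }
    if (is.null(best) || cand$value < best$value ||
        (!best$converged && cand$converged && cand$value <= best$value + reltol))
      best <- cand
  }
  ## quasi-Newton polish: the simplex converges on the NLL value, which
  ## leaves ~sqrt(reltol)-scale error in the coefficients
  o2 <- tryCatch(stats::optim(best$par, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-14)),
                 error = function(e) NULL)
  if (!is.null(o2) && o2$value <= best$value + reltol)
    best <- list(par = o2$par, value = min(o2$value, best$value),
                 converged = best$converged || o2$convergence == 0)
  par <- best$par
  if (nb && par[length(par)] > 25) par[length(par)] <- 25
  ## intercepts whose member sites have all-zero counts are unidentified
  ## (the log-link MLE sits at -Inf): cap at log(eps) and warn
  if (link == "log") {
    X <- designMatrix(model, responses)
    rv <- .responseVector(model, responses)
    icols <- which(names(par) != "log_k" & !grepl("^slope\\[", names(par)))
    capped <- FALSE
    for (j in icols) {
      member <- X[, j] != 0
      if (any(member) && all(rv$y[member] == 0)) {
        par[j] <- log(.MU_EPS)
        capped <- TRUE
      }
    }
    if (capped) {
      warning("degenerate all-zero component data: coefficient capped at log(1e-9)")
      best$value <- obj(par)
    }
  }
  logL <- -best$value
  if (logL > 1e-8)
    warning("positive log-likelihood from a discrete model: check inputs")
  new("FittedModel", model = model, params = par, logL = logL,
      K = model@K, n = nrow(responses), converged = isTRUE(best$converged))
}

#' @describeIn fitModel display a fitted model
#' @param object a FittedModel
#' @export
setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel %s (%s, %s): logL = %.4f, K = %d, n = %d%s\n",
              object@model@model_id, object@model@response,
              object@model@distribution, object@logL, object@K, object@n,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  print(round(object@params, 4))
  invisible(NULL)
})

#' Coefficients of a fitted candidate model
#' @param object a \linkS4class{FittedModel}
#' @param ... unused
#' @return named numeric vector on the link scale
#' @export
setMethod("coef", "FittedModel", function(object, ...) object@params)

#' Log-likelihood of a fitted candidate model
#' @param object a \linkS4class{FittedModel}
#' @param ... unused
#' @return an object of class "logLik" with df = K and nobs = n
#' @export
setMethod("logLik", "FittedModel", function(object, ...) {
  structure(object@logL, df = object@K, nobs = object@n, class = "logLik")
})
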