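# Radioligand homologous-competition binding: the one-site no-depletion
# model, weighted nonlinear least-squares fitting of (Kd, Rt, NS), the
# three-sample dissection of specific binding into reversible and
# irreversible components, and a curve simulator for recovery tests.

#' One-site homologous-competition binding model
#'
#' Bound hot ligand when a trace concentration `hot` of labeled toxin
#' competes with unlabeled toxin at concentration `comp` for a single
#' class of sites, both species having the same affinity and with no
#' ligand depletion:
#' `B = Rt * H / (Kd + H + C) + NS * H`.
#'
#' @param kd equilibrium dissociation constant, nM (> 0)
#' @param rt concentration of binding sites, pmol/mg (>= 0)
#' @param ns nonspecific-binding slope (signal bound per nM of hot ligand,
#'   not displaceable; >= 0)
#' @param hot hot-ligand concentration, nM (>= 0); assays here use 1 nM
#' @param comp competitor concentration(s), nM (>= 0), vectorized
#' @return bound signal, pmol/mg
#' @export
model_bound <- function(kd, rt, ns, hot, comp) {
  if (kd <= 0) stop("`kd` must be > 0", call. = FALSE)
  if (rt < 0 || ns < 0) stop("`rt` and `ns` must be >= 0", call. = FALSE)
  if (hot < 0 || any(comp < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  rt * hot / (kd + hot + comp) + ns * hot
}

#' Fit a homologous-competition curve
#'
#' Weighted nonlinear least squares under [model_bound()].  The default
#' weighting assumes proportional (counting-instrument) error: weights
#' `1 / fitted^2`, applied by iterative reweighting from an initial
#' unweighted fit.  Standard errors are the asymptotic errors from the
#' final fit's Jacobian.
#'
#' @param curve data frame with columns `conc` (competitor, nM) and
#'   `bound`; at least 4 distinct concentrations
#' @param hot hot-ligand concentration, nM (default 1)
#' @param weights `"proportional"` (default) or `"none"`
#' @param reweight_iter reweighting iterations (default 2)
#' @return object of class `binding_fit`: list with `kd`, `rt`, `ns`,
#'   `se` (named vector), `converged`, `degenerate`, and the `nls` fit
#' @export
fit_homologous_competition <- function(curve, hot = 1,
                                       weights = c("proportional", "none"),
                                       reweight_iter = 2L) {
  weights <- match.arg(weights)
  if (!all(c("conc", "bound") %in% names(curve))) {
    stop("`curve` must have columns conc and bound", call. = FALSE)
  }
  curve <- curve[stats::complete.cases(curve[, c("conc", "bound")]), ]
  if (length(unique(curve$conc)) < 4L) {
    stop("need at least 4 distinct competitor concentrations", call. = FALSE)
  }
  if (any(curve$conc < 0)) stop("concentrations must be >= 0", call. = FALSE)

  fail <- function(degenerate) {
    structure(list(kd = NA_real_, rt = NA_real_, ns = NA_real_,
                   se = c(kd = NA_real_, rt = NA_real_, ns = NA_real_),
                   converged = FALSE, degenerate = degenerate, fit = NULL,
                   data = curve, hot = hot),
              class = "binding_fit")
  }
  rng <- max(curve$bound) - min(curve$bound)
  if (rng <= max(1e-12, 1e-9 * max(abs(curve$bound)))) return(fail(TRUE))

  # starting values: NS from the high-competitor plateau, Kd from the
  # half-displacement concentration (C50 = Kd + H), Rt from the zero-
  # competitor amplitude
  b_lo <- min(curve$bound); b_hi <- max(curve$bound)
  ns0 <- max(b_lo / max(hot, 1e-9) * 0.8, 1e-9)
  half <- (b_hi + b_lo) / 2
  o <- order(curve$conc)
  c50 <- stats::approx(curve$bound[o], curve$conc[o], xout = half,
                       ties = mean)$y
  kd0 <- max(ifelse(is.na(c50), stats::median(curve$conc[curve$conc > 0]),
                    c50 - hot), hot / 10, 1e-3)
  rt0 <- max((b_hi - ns0 * hot) * (kd0 + hot) / max(hot, 1e-9), 1e-6)

  do_fit <- function(w) {
    tryCatch(
      stats::nls(bound ~ rt * hot / (kd + hot + conc) + ns * hot,
                 data = curve,
                 start = list(kd = kd0, rt = rt0, ns = ns0),
                 weights = w, algorithm = "port",
                 lower = c(kd = 1e-6, rt = 0, ns = 0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  }
  fit <- do_fit(rep(1, nrow(curve)))
  if (weights == "proportional" && !is.null(fit)) {
    for (i in seq_len(reweight_iter)) {
      w <- 1 / pmax(stats::fitted(fit), 1e-9)^2
      refit <- do_fit(w)
      if (is.null(refit)) break
      fit <- refit
    }
  }
  if (is.null(fit)) return(fail(FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA, rt = NA, ns = NA))
  structure(list(kd = unname(cf["kd"]), rt = unname(cf["rt"]),
                 ns = unname(cf["ns"]),
                 se = c(kd = unname(se["kd"]), rt = unname(se["rt"]),
                        ns = unname(se["ns"])),
                 converged = fit$convInfo$isConv, degenerate = FALSE,
                 fit = fit, data = curve, hot = hot),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("binding_fit: degenerate curve (no displacement), not fitted\n")
  } else if (!x$converged) {
    cat("binding_fit: did not converge\n")
  } else {
    cat(sprintf("binding_fit: Kd = %.3g +/- %.2g nM, Rt = %.3g +/- %.2g pmol/mg, NS = %.3g\n",
                x$kd, x$se["kd"], x$rt, x$se["rt"], x$ns))
  }
  invisible(x)
}

#' Dissect specific binding into reversible and irreversible components
#'
#' Three-sample design: sample one measures total binding; sample two,
#' with excess unlabeled toxin from the start, measures nonspecific
#' binding; sample three, with excess unlabeled toxin added mid-
#' incubation, measures irreversible plus nonspecific binding.  Then
#' specific = total - nonspecific, irreversible = sample3 - nonspecific,
#' reversible = specific - irreversible.  Negative components are clamped
#' to zero with a warning while preserving the identity
#' reversible + irreversible = specific.
#'
#' @param total bound signal of the total-binding sample
#' @param nonspecific bound signal of the nonspecific sample
#' @param irreversible_sample bound signal of the delayed-competitor sample
#' @return list with `total`, `nonspecific`, `specific`, `irreversible`,
#'   `reversible`, and `clamped` (logical)
#' @export
dissect_binding <- function(total, nonspecific, irreversible_sample) {
  specific <- total - nonspecific
  irreversible <- irreversible_sample - nonspecific
  clamped <- specific < 0 || irreversible < 0 || irreversible > max(specific, 0)
  specific_c <- max(specific, 0)
  irreversible_c <- min(max(irreversible, 0), specific_c)
  if (clamped) {
    warning("negative or inconsistent binding component clamped",
            call. = FALSE)
  }
  list(total = total, nonspecific = nonspecific,
       specific = specific_c, irreversible = irreversible_c,
       reversible = specific_c - irreversible_c, clamped = clamped)
}

#' Simulate replicate homologous-competition curves
#'
#' Bound values are the model prediction times `(1 + eps)` with
#' `eps ~ Normal(0, cv)` — proportional noise as produced by counting
#' instruments.
#'
#' @inheritParams model_bound
#' @param conc competitor concentration grid, nM
#' @param cv coefficient of variation of the proportional noise (>= 0)
#' @param n_rep number of replicate curves
#' @param seed integer seed
#' @return list of `n_rep` data frames with columns conc, bound, replicate
#' @export
simulate_binding_curve <- function(kd, rt, ns, hot, conc, cv = 0.05,
                                   n_rep = 1L, seed = 1L) {
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  stop_if_not_scalar_count(n_rep, "n_rep")
  mu <- model_bound(kd, rt, ns, hot, conc)
  with_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      eps <- stats::rnorm(length(conc), 0, cv)
      data.frame(conc = conc, bound = mu * (1 + eps), replicate = r)
    })
  })
}

#' Read a binding-curve CSV
#' @param path CSV with columns competitor_nM, bound and optionally
#'   replicate
#' @return data frame with columns conc, bound, replicate
#' @export
read_binding_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("competitor_nM", "bound") %in% names(df))) {
    stop("binding CSV must have columns competitor_nM and bound",
         call. = FALSE)
  }
  data.frame(conc = df$competitor_nM, bound = df$bound,
             replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}
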