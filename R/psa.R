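#' Set a value in a nested parameter list by dotted path
#' @noRd
set_by_path <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    params[[keys]] <- value
  } else {
    params[[keys[1]]][[keys[2]]] <- value
  }
  params
}

#' Draw one parameter set for the probabilistic sensitivity analysis
#'
#' Samples every parameter that carries a non-degenerate distribution spec
#' in `params$psa` (independent draws) and rebuilds the bundle. The
#' bleed-state utility is re-derived as `u_af - d_bleed` after sampling.
#' Uses the current RNG state; seed via `set.seed()` or [run_psa()].
#'
#' @param params an `af_params` object.
#' @return an `af_params` object with sampled values (not re-validated;
#'   structurally impossible draws surface as model-consistency errors when
#'   the model is run, and are excluded by [run_psa()]).
#' @export
sample_parameters <- function(params) {
  stopifnot(inherits(params, "af_params"))
  out <- params
  for (nm in names(params$psa)) {
    spec <- params$psa[[nm]]
    if (spec$family == "fixed") next
    out <- set_by_path(out, nm, draw_spec(spec, 1))
  }
  out$utilities$u_major_bleed <-
    min(max(out$utilities$u_af - out$utilities$d_bleed, 0), 1)
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo reruns of the full cascade-cohort-CEA pipeline under sampled
#' parameter sets. Event probabilities, utilities, event costs, treatment
#' effects and persistence are drawn from their distributions; treatment
#' costs, total screening costs and the cascade inputs stay fixed, so the
#' cohort size and screening cost per patient are constant across draws.
#' Because event dynamics do not depend on the drug mix (equal efficacy
#' assumed), each draw propagates the two arm traces once and prices them
#' under every requested mix.
#'
#' @param params an `af_params` object.
#' @param lifetable an `af_life_table` (calibrated if `NULL`).
#' @param n number of Monte Carlo iterations.
#' @param seed RNG seed; recorded in the result.
#' @param mixes named numeric vector of NOAC fractions to price.
#' @param wtp willingness-to-pay threshold for the cost-effective fraction.
#' @return an `af_psa` object: `points` (data frame with `iteration`,
#'   `mix`, `delta_qaly`, `delta_cost`, `nmb`, per patient, discounted),
#'   `n`, `n_excluded`, `seed`, `wtp`, `summary` (fraction cost-effective
#'   per mix).
#' @export
run_psa <- function(params, lifetable = NULL, n = 10000, seed = 1,
                    mixes = c(noac = 1, warfarin = 0, mix5050 = 0.5),
                    wtp = params$wtp) {
  stopifnot(inherits(params, "af_params"), n >= 1)
  if (is.null(lifetable)) lifetable <- calibrated_life_table(params)
  cascade <- run_cascade(params)
  screening_pp <- if (isTRUE(params$include_screening_cost_in_icer)) {
    cascade$cost_total / cascade$cohort_size
  } else 0

  set.seed(seed)
  n_mix <- length(mixes)
  dq <- matrix(NA_real_, n, n_mix)
  dc <- matrix(NA_real_, n, n_mix)
  excluded <- 0L
  for (i in seq_len(n)) {
    draw <- sample_parameters(params)
    res <- tryCatch({
      tr_s <- run_cohort(draw, "screening", lifetable)
      tr_n <- run_cohort(draw, "no_screening", lifetable)
      vapply(mixes, function(mx) {
        s <- trace_outcomes(tr_s, draw, mix = mx, per_cycle = FALSE)$totals$discounted
        b <- trace_outcomes(tr_n, draw, mix = mx, per_cycle = FALSE)$totals$discounted
        c(s$qaly - b$qaly, s$cost - b$cost + screening_pp)
      }, numeric(2))
    }, error = function(e) NULL)
    if (is.null(res)) {
      excluded <- excluded + 1L
    } else {
      dq[i, ] <- res[1, ]
      dc[i, ] <- res[2, ]
    }
  }
  keep <- !is.na(dq[, 1])
  points <- data.frame(
    iteration = rep(which(keep), n_mix),
    mix = rep(names(mixes), each = sum(keep)),
    delta_qaly = as.vector(dq[keep, ]),
    delta_cost = as.vector(dc[keep, ])
  )
  points$nmb <- wtp * points$delta_qaly - points$delta_cost
  frac_ce <- tapply(points$nmb >= 0, points$mix, mean)[names(mixes)]
  structure(list(points = points, n = n, n_excluded = excluded, seed = seed,
                 wtp = wtp, mixes = mixes, summary = frac_ce),
            class = "af_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations whose
#' net monetary benefit is non-negative.
#'
#' @param psa an `af_psa` object, or a data frame with `delta_qaly` and
#'   `delta_cost` (a `mix` column is honoured if present).
#' @param wtp_grid willingness-to-pay values (US$/QALY).
#' @return data frame with `mix`, `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20000, by = 500)) {
  points <- if (inherits(psa, "af_psa")) psa$points else psa
  if (nrow(points) == 0) stop("no PSA points", call. = FALSE)
  if (is.null(points$mix)) points$mix <- "all"
  out <- expand.grid(mix = unique(points$mix), wtp = wtp_grid,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prob_cost_effective <- mapply(function(mx, w) {
    p <- points[points$mix == mx, ]
    mean(w * p$delta_qaly - p$delta_cost >= 0)
  }, out$mix, out$wtp)
  out[order(out$mix, out$wtp), ]
}

#' Write PSA plane points to CSV
#' @param psa an `af_psa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(psa$points, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.af_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (%d excluded), seed %d\n",
              x$n, x$n_excluded, x$seed))
  for (mname in names(x$mixes)) {
    p <- x$points[x$points$mix == mname, ]
    cat(sprintf("  %-9s mean dQALY %.3f, mean dCost $%7.0f, P(CE at $%s/QALY) = %.3f\n",
                mname, mean(p$delta_qaly), mean(p$delta_cost),
                format(x$wtp, big.mark = ","), x$summary[[mname]]))
  }
  invisible(x)
}

#' Plot the cost-effectiveness plane or acceptability curve
#'
#' @param x an `af_psa` object.
#' @param type `"plane"` (per-patient incremental cost vs QALY scatter with
#'   the WTP line) or `"ceac"`.
#' @param wtp_grid WTP grid for the CEAC.
#' @param ... further arguments passed to the base plotting functions.
#' @return `x`, invisibly.
#' @export
plot.af_psa <- function(x, type = c("plane", "ceac"),
                        wtp_grid = seq(0, 20000, by = 500), ...) {
  type <- match.arg(type)
  mixes <- names(x$mixes)
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(mixes)), "Dark 3")[seq_along(mixes)],
                          mixes)
  if (type == "plane") {
    p <- x$points
    plot(p$delta_qaly, p$delta_cost, col = cols[p$mix], pch = 16, cex = 0.4,
         xlab = "Incremental QALYs per patient",
         ylab = "Incremental cost per patient (US$)",
         main = "Cost-effectiveness plane", ...)
    graphics::abline(0, x$wtp, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey70")
    graphics::legend("topleft", legend = mixes, col = cols, pch = 16, bty = "n")
  } else {
    cc <- ceac(x, wtp_grid)
    plot(NA, xlim = range(wtp_grid), ylim = c(0, 1),
         xlab = "Willingness to pay (US$/QALY)",
         ylab = "Probability cost-effective",
         main = "Cost-effectiveness acceptability curve", ...)
    for (mname in mixes) {
      ci <- cc[cc$mix == mname, ]
      graphics::lines(ci$wtp, ci$prob_cost_effective, col = cols[mname], lwd = 2)
    }
    graphics::abline(v = x$wtp, lty = 2, col = "grey50")
    graphics::legend("bottomright", legend = mixes, col = cols, lwd = 2, bty = "n")
  }
  invisible(x)
}
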