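#' Site metadata
#'
#' One row per tower. Roughness length and zero-plane displacement default to
#' the canopy-height fractions used throughout the package: `z0 = 0.1 hc`,
#' `d = 0.67 hc`.
#'
#' @param site_id character site identifier.
#' @param igbp integer IGBP class code of the site.
#' @param lat,lon location in degrees.
#' @param zm measurement height (m).
#' @param hc canopy height (m).
#' @param z0 roughness length (m); default `0.1 * hc`.
#' @param d zero-plane displacement (m); default `0.67 * hc`.
#' @return one-row tibble.
#' @export
site_meta <- function(site_id, igbp, lat, lon, zm, hc,
                      z0 = NULL, d = NULL) {
  r <- derive_roughness(hc)
  z0 <- z0 %||% r$z0
  d <- d %||% r$d
  if (zm <= d) abort("measurement height zm must exceed displacement d.")
  tibble(site_id = site_id, igbp = as.integer(igbp), lat = lat, lon = lon,
         zm = zm, hc = hc, z0 = z0, d = d)
}

#' Roughness parameters from canopy height
#'
#' Standard fractions: roughness length is 10% and zero-plane displacement
#' 67% of canopy height.
#'
#' @param hc canopy height in metres (vectorized).
#' @return tibble with columns `z0` and `d` in metres.
#' @export
derive_roughness <- function(hc) {
  if (any(!is.finite(hc)) || any(hc <= 0)) {
    abort("canopy height hc must be positive.")
  }
  tibble(z0 = 0.1 * hc, d = 0.67 * hc)
}

#' Obukhov length from surface-layer bulk variables
#'
#' `L = -rho * cp * T * ustar^3 / (k * g * H)` with k = 0.4, g = 9.81 m s^-2,
#' cp = 1004 J kg^-1 K^-1 and air density from the ideal gas law at the given
#' pressure and temperature. The sign is opposite to the sensible heat flux:
#' upward flux (unstable) gives `L < 0`. A zero heat flux returns `Inf`
#' (neutral sentinel).
#'
#' @param ustar friction velocity (m s^-1).
#' @param ta air temperature (deg C).
#' @param pa air pressure (kPa).
#' @param h sensible heat flux (W m^-2).
#' @return Obukhov length in metres (vectorized).
#' @export
obukhov_length <- function(ustar, ta, pa, h) {
  if (any(ustar <= 0, na.rm = TRUE)) abort("ustar must be positive.")
  k <- 0.4
  g <- 9.81
  cp <- 1004
  rd <- 287.05
  tk <- ta + 273.15
  rho <- pa * 1000 / (rd * tk)
  out <- -rho * cp * tk * ustar^3 / (k * g * h)
  out[h == 0] <- Inf
  out
}

#' Boundary-layer height per record
#'
#' Passes through any measured `pblh`. For missing values under stable or
#' neutral stratification (`L > 0`) it applies the equilibrium diagnostic
#' `h = L / 3.8 * (-1 + sqrt(1 + 2.28 * ustar / (f * L)))` with the Coriolis
#' parameter `f` at the site latitude; under convective conditions (`L < 0`)
#' no equilibrium height exists and the configured default is used. Within
#' 5 degrees of the equator the Coriolis parameter is too small for the
#' stable diagnostic, which then falls back to the default with a warning.
#'
#' @param records met tibble with columns `ustar`, `L` and optionally `pblh`.
#' @param lat site latitude in degrees.
#' @param convective_default boundary-layer height (m) used when `L < 0`
#'   or the diagnostic is unavailable.
#' @return `records` with the `pblh` column filled.
#' @export
estimate_pblh <- function(records, lat, convective_default = 2000) {
  if (!"pblh" %in% names(records)) records$pblh <- NA_real_
  miss <- is.na(records$pblh)
  if (!any(miss)) {
    return(records)
  }
  if (abs(lat) < 5) {
    warn("latitude within 5 degrees of the equator: Coriolis parameter too small for the stable diagnostic; using the convective default.")
    records$pblh[miss] <- convective_default
    return(records)
  }
  f <- 2 * 7.2921e-5 * sin(lat * pi / 180)
  L <- records$L[miss]
  u <- records$ustar[miss]
  stable <- is.finite(L) & L > 0
  est <- rep(convective_default, sum(miss))
  est[stable] <- L[stable] / 3.8 *
    (-1 + sqrt(1 + 2.28 * u[stable] / (abs(f) * L[stable])))
  records$pblh[miss] <- est
  records
}

#' Quality filter for footprint-model validity
#'
#' Keeps the records within the footprint parameterization's validity bounds:
#' `zm / L >= -15.5` (not too strongly convective) and
#' `20 z0 < zm < 0.8 pblh` (measurement height inside the surface layer and
#' well below the boundary-layer top). Records failing several rules are
#' attributed to the first failed rule in the order stability, lower height
#' bound, upper height bound. The per-rule counts are attached as the
#' `"filter_report"` attribute (see [filter_report()]).
#'
#' @param records met tibble with columns `L` and `pblh`.
#' @param meta a [site_meta()] row providing `zm` and `z0`.
#' @return the kept records, with a `filter_report` attribute.
#' @export
qc_filter <- function(records, meta) {
  zm <- meta$zm
  z0 <- meta$z0
  fail_stab <- records$L < 0 & zm / records$L < -15.5
  fail_low <- !fail_stab & (20 * z0 >= zm)
  fail_high <- !fail_stab & !fail_low & (zm >= 0.8 * records$pblh)
  keep <- !(fail_stab | fail_low | fail_high)
  report <- tibble(
    n_input = nrow(records),
    n_kept = sum(keep),
    n_rejected_stability = sum(fail_stab),
    n_rejected_height_low = sum(fail_low),
    n_rejected_height_high = sum(fail_high)
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' @rdname qc_filter
#' @param x records returned by [qc_filter()].
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    abort("no filter report attached; run qc_filter() first.")
}

sigma_v_covariates <- c("ustar", "ws", "sw_in", "pa", "z0", "zm", "hc")

#' Fit the lateral-wind-speed predictor
#'
#' Random-forest regression of `sigma_v` on the seven micrometeorological and
#' site covariates (friction velocity, wind speed, incoming shortwave,
#' pressure, roughness length, measurement and canopy height), evaluated by
#' k-fold cross-validation. The pooled out-of-fold R^2 and mean absolute
#' error are recorded on the returned model.
#'
#' @param training tibble with the 7 covariates and a `sigma_v` column.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for fold assignment and tree growing.
#' @param num_trees number of trees in the ensemble.
#' @param mtry covariates tried per split; with only seven smooth drivers a
#'   value above the square-root default markedly improves fit.
#' @return a `sigma_v_model` object; see [tidy.sigma_v_model()].
#' @export
fit_sigma_v <- function(training, folds = 5L, seed = 1L, num_trees = 100L,
                        mtry = 5L) {
  missing_cols <- setdiff(c(sigma_v_covariates, "sigma_v"), names(training))
  if (length(missing_cols)) {
    abort(paste0("training table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (folds < 2L) abort("need at least 2 folds.")
  dat <- as.data.frame(training[, c(sigma_v_covariates, "sigma_v")])
  n <- nrow(dat)
  withr::with_seed(as.integer(seed), {
    fold_id <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (k in seq_len(folds)) {
      fit_k <- ranger::ranger(
        sigma_v ~ ., data = dat[fold_id != k, ],
        num.trees = num_trees, mtry = mtry, seed = seed + k
      )
      pred[fold_id == k] <-
        predict(fit_k, dat[fold_id == k, ])$predictions
    }
    cv_r2 <- 1 - sum((dat$sigma_v - pred)^2) /
      sum((dat$sigma_v - mean(dat$sigma_v))^2)
    cv_mae <- mean(abs(dat$sigma_v - pred))
    fold_stats <- tibble(fold = seq_len(folds)) |>
      mutate(
        r2 = map_dbl(.data$fold, function(k) {
          i <- fold_id == k
          1 - sum((dat$sigma_v[i] - pred[i])^2) /
            sum((dat$sigma_v[i] - mean(dat$sigma_v[i]))^2)
        }),
        mae = map_dbl(.data$fold, function(k) {
          i <- fold_id == k
          mean(abs(dat$sigma_v[i] - pred[i]))
        })
      )
    model <- ranger::ranger(
      sigma_v ~ ., data = dat, num.trees = num_trees, mtry = mtry,
      importance = "impurity", seed = seed
    )
    structure(
      list(
        model = model, covariates = sigma_v_covariates,
        cv_folds = folds, cv_r2 = cv_r2, cv_mae = cv_mae,
        fold_stats = fold_stats, n = n, seed = as.integer(seed)
      ),
      class = "sigma_v_model"
    )
  })
}

#' @export
print.sigma_v_model <- function(x, ...) {
  cat(sprintf(
    "<sigma_v_model> %d trees on %d rows; %d-fold CV R^2 = %.3f, MAE = %.3f m s^-1\n",
    x$model$num.trees, x$n, x$cv_folds, x$cv_r2, x$cv_mae
  ))
  invisible(x)
}

#' Fill missing lateral wind speeds with model predictions
#'
#' Only records whose `sigma_v` is missing are predicted; measured values are
#' never overwritten. Predictions are floored at a small positive value.
#'
#' @param model a fitted [fit_sigma_v()] model.
#' @param records met tibble; a missing `sigma_v` column is treated as
#'   all-missing.
#' @param meta a [site_meta()] row supplying `z0`, `zm`, `hc` covariates.
#' @return `records` with `sigma_v` filled.
#' @export
predict_sigma_v <- function(model, records, meta) {
  stopifnot(inherits(model, "sigma_v_model"))
  if (!"sigma_v" %in% names(records)) records$sigma_v <- NA_real_
  miss <- is.na(records$sigma_v)
  if (!any(miss)) {
    return(records)
  }
  newdata <- data.frame(
    ustar = records$ustar[miss], ws = records$ws[miss],
    sw_in = records$sw_in[miss], pa = records$pa[miss],
    z0 = meta$z0, zm = meta$zm, hc = meta$hc
  )
  p <- predict(model$model, newdata)$predictions
  records$sigma_v[miss] <- pmax(p, 1e-3)
  records
}
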