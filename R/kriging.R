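#' Project geographic coordinates to planar kilometres
#'
#' Equirectangular projection about the mean latitude: x = R cos(lat0)
#' (lon - lon0), y = R (lat - lat0), in km. Adequate for variography at
#' continental scale; kriging assumes planar coordinates.
#'
#' @param longitude,latitude decimal degrees.
#' @param origin optional c(lon0, lat0); defaults to the mean.
#' @return data.frame with columns `x`, `y` (km) and attributes `origin`.
#' @export
project_equirectangular <- function(longitude, latitude, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(longitude), mean(latitude))
  R <- 6371
  x <- R * cos(origin[2] * pi / 180) * (longitude - origin[1]) * pi / 180
  y <- R * (latitude - origin[2]) * pi / 180
  out <- data.frame(x = x, y = y)
  attr(out, "origin") <- origin
  out
}

variogram_families <- list(
  spherical = function(h, nugget, psill, range) {
    g <- ifelse(h >= range, nugget + psill,
                nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3))
    ifelse(h == 0, 0, g)
  },
  exponential = function(h, nugget, psill, range) {
    ifelse(h == 0, 0, nugget + psill * (1 - exp(-3 * h / range)))
  },
  gaussian = function(h, nugget, psill, range) {
    ifelse(h == 0, 0, nugget + psill * (1 - exp(-3 * (h / range)^2)))
  }
)

#' Fit a variogram model to spatial point data
#'
#' Computes the empirical semivariogram (pair differences binned by
#' distance up to half the maximum pair distance), then fits spherical,
#' exponential and gaussian models by weighted least squares (weights =
#' pair counts / squared distance, the conventional auto-fitting
#' weighting) and returns the family with the lowest weighted SSE.
#' A constant field yields a flagged degenerate pure-nugget model.
#'
#' @param points data.frame with columns `x`, `y`, `value` (planar
#'   coordinates, e.g. from [project_equirectangular()]).
#' @param n_bins number of distance bins (default 12).
#' @param families candidate model families (default all three); note the
#'   `range` parameter is family-specific (the practical range for the
#'   exponential and gaussian forms, the exact plateau for the
#'   spherical).
#' @return list of class `variogram_model`: `model_family`, `nugget`,
#'   `sill` (= nugget + partial sill), `psill`, `range`, `degenerate`,
#'   `empirical` (bin table).
#' @export
fit_variogram <- function(points, n_bins = 12,
                          families = names(variogram_families)) {
  if (nrow(points) < 5) stop("fit_variogram: need at least 5 points")
  dx <- stats::dist(points[, c("x", "y")])
  dv <- stats::dist(points$value)^2 / 2
  h <- as.numeric(dx)
  gm <- as.numeric(dv)
  if (stats::var(points$value) == 0) {
    res <- list(model_family = "spherical", nugget = 0, sill = 0,
                psill = 0, range = max(h) / 2, degenerate = TRUE,
                empirical = NULL)
    class(res) <- "variogram_model"
    return(res)
  }
  cutoff <- max(h) / 2
  use <- h <= cutoff & h > 0
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(h[use], br, include.lowest = TRUE)
  emp <- data.frame(
    dist = tapply(h[use], bin, mean),
    gamma = tapply(gm[use], bin, mean),
    n = as.integer(table(bin))
  )
  emp <- emp[!is.na(emp$gamma) & emp$n > 0, ]
  s2 <- stats::var(points$value)
  best <- NULL
  for (fam in families) {
    fn <- variogram_families[[fam]]
    obj <- function(par) {
      g <- fn(emp$dist, par[1], par[2], par[3])
      sum(emp$n / emp$dist^2 * (emp$gamma - g)^2)
    }
    # multi-start on the range to avoid local minima
    for (r0 in cutoff * c(0.25, 0.5, 1)) {
      init <- c(nugget = min(emp$gamma) / 2, psill = s2, range = r0)
      opt <- try(stats::optim(init, obj, method = "L-BFGS-B",
                              lower = c(0, 1e-10, max(emp$dist) * 1e-3),
                              upper = c(Inf, Inf, cutoff * 10)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) {
        best <- list(value = opt$value, fam = fam, par = opt$par)
      }
    }
  }
  if (is.null(best)) stop("fit_variogram: all fits failed")
  res <- list(model_family = best$fam,
              nugget = unname(best$par[1]),
              sill = unname(best$par[1] + best$par[2]),
              psill = unname(best$par[2]),
              range = unname(best$par[3]),
              degenerate = FALSE,
              empirical = emp)
  class(res) <- "variogram_model"
  res
}

#' Ordinary kriging over a grid
#'
#' Solves the ordinary-kriging system (semivariogram matrix with Lagrange
#' multiplier; weights constrained to sum to one) at each grid node and
#' reports prediction and kriging variance. Duplicate data points are
#' averaged first with a warning. With a zero nugget the predictor
#' interpolates the data exactly.
#'
#' @param points data.frame with `x`, `y`, `value`.
#' @param model a [fit_variogram()] result (or compatible list).
#' @param grid data.frame with columns `x`, `y`; defaults to a regular
#'   grid over the point bounding box with 10% margin.
#' @param grid_n grid nodes per side when `grid` is NULL.
#' @return data.frame: `x`, `y`, `prediction`, `variance`,
#'   `weight_sum` (one per node, equals 1 up to numerical tolerance).
#' @export
krige_surface <- function(points, model, grid = NULL, grid_n = 25) {
  if (anyDuplicated(points[, c("x", "y")])) {
    warning("krige_surface: duplicate locations averaged")
    points <- stats::aggregate(value ~ x + y, data = points, FUN = mean)
  }
  if (is.null(grid)) {
    rx <- range(points$x); ry <- range(points$y)
    mx <- diff(rx) * 0.1; my <- diff(ry) * 0.1
    grid <- expand.grid(
      x = seq(rx[1] - mx, rx[2] + mx, length.out = grid_n),
      y = seq(ry[1] - my, ry[2] + my, length.out = grid_n))
  }
  fn <- variogram_families[[model$model_family]]
  gamma_fn <- function(h) fn(h, model$nugget, model$psill, model$range)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points[, c("x", "y")]))
  A <- rbind(cbind(gamma_fn(D), 1), c(rep(1, n), 0))
  diag(A)[seq_len(n)] <- 0
  Ai <- solve(A)
  z <- points$value
  pred <- var_k <- wsum <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    h0 <- sqrt((points$x - grid$x[i])^2 + (points$y - grid$y[i])^2)
    g0 <- gamma_fn(h0)
    sol <- Ai %*% c(g0, 1)
    w <- sol[seq_len(n)]
    mu <- sol[n + 1]
    pred[i] <- sum(w * z)
    var_k[i] <- max(sum(w * g0) + mu, 0)
    wsum[i] <- sum(w)
  }
  data.frame(x = grid$x, y = grid$y, prediction = pred,
             variance = var_k, weight_sum = wsum)
}

#' Interpolate regional allele-frequency clines
#'
#' Chains [mean_regional_frequency()] output through projection,
#' variogram fitting and ordinary kriging, returning the interpolated
#' surface in geographic coordinates.
#'
#' @param freqs output of [mean_regional_frequency()].
#' @param grid_step grid spacing in degrees (default 0.5).
#' @return list: `surface` (lon, lat, prediction, variance),
#'   `variogram`.
#' @export
krige_allele_frequencies <- function(freqs, grid_step = 0.5) {
  ok <- stats::complete.cases(
    freqs[, c("longitude", "latitude", "mean_freq")])
  f <- freqs[ok, ]
  pr <- project_equirectangular(f$longitude, f$latitude)
  pts <- data.frame(x = pr$x, y = pr$y, value = f$mean_freq)
  vg <- fit_variogram(pts)
  rx <- range(f$longitude); ry <- range(f$latitude)
  mx <- diff(rx) * 0.1; my <- diff(ry) * 0.1
  lonlat <- expand.grid(
    lon = seq(rx[1] - mx, rx[2] + mx, by = grid_step),
    lat = seq(ry[1] - my, ry[2] + my, by = grid_step))
  gpr <- project_equirectangular(lonlat$lon, lonlat$lat,
                                 origin = attr(pr, "origin"))
  surf <- krige_surface(pts, vg, grid = data.frame(x = gpr$x, y = gpr$y))
  list(surface = data.frame(lon = lonlat$lon, lat = lonlat$lat,
                            prediction = surf$prediction,
                            variance = surf$variance),
       variogram = vg)
}
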