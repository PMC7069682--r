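#' Construct a monthly climate series for one site
#'
#' @param site site label.
#' @param latitude decimal degrees, within \[-60, 60\].
#' @param temperature 12 monthly mean temperatures (deg C, Jan-Dec).
#' @param rainfall 12 monthly rainfall totals (mm, >= 0).
#' @param whc soil water holding capacity (mm, default 100).
#' @return object of class `climate_series`.
#' @export
climate_series <- function(site, latitude, temperature, rainfall, whc = 100) {
  stopifnot(length(temperature) == 12, length(rainfall) == 12)
  if (any(!is.finite(temperature)) || any(!is.finite(rainfall)))
    stop("non-finite climate values")
  if (any(rainfall < 0)) stop("negative rainfall")
  if (whc <= 0) stop("WHC must be positive")
  if (latitude < -60 || latitude > 60)
    stop("latitude outside [-60, 60]: day-length correction not supported")
  structure(list(site = site, latitude = latitude,
                 temperature = as.numeric(temperature),
                 rainfall = as.numeric(rainfall), whc = whc),
            class = "climate_series")
}

#' Read per-site climate series from a long-format CSV
#'
#' Columns: `site`, `latitude`, `month` (1-12), `temperature`, `rainfall`.
#'
#' @param path CSV file path.
#' @param whc water holding capacity applied to every site (mm).
#' @return named list of `climate_series`.
#' @export
read_climate_csv <- function(path, whc = 100) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "latitude", "month", "temperature", "rainfall")
  if (!all(need %in% names(df)))
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$site), function(s) {
    s <- s[order(s$month), ]
    if (!identical(as.integer(s$month), 1:12))
      stop("site ", s$site[1], ": months must be exactly 1..12")
    climate_series(s$site[1], s$latitude[1], s$temperature, s$rainfall, whc)
  })
  out[unique(df$site)]
}

DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
MID_MONTH_DAY <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2

## Mean possible sunshine hours per month from solar-declination geometry.
day_length_hours <- function(latitude) {
  phi <- latitude * pi / 180
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + MID_MONTH_DAY) / 365)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 / pi * acos(x)
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from mean temperature via the annual heat index
#' I = sum (T/5)^1.514 over months with T > 0 and exponent
#' a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239. Unadjusted PET is
#' 16 (10 T / I)^a for 0 < T <= 26.5 and the hot-month polynomial
#' -415.85 + 32.24 T - 0.43 T^2 above 26.5 deg C; 0 at or below freezing.
#' Each month is then adjusted by (day length / 12) x (days in month / 30),
#' with day length from solar-declination geometry at the site latitude.
#'
#' @param series a `climate_series`.
#' @return numeric vector of 12 monthly PET values (mm).
#' @export
thornthwaite_pet <- function(series) {
  stopifnot(inherits(series, "climate_series"))
  Tm <- series$temperature
  i_m <- ifelse(Tm > 0, (Tm / 5)^1.514, 0)
  I <- sum(i_m)
  pet <- numeric(12)
  if (I > 0) {
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    mid <- Tm > 0 & Tm <= 26.5
    pet[mid] <- 16 * (10 * Tm[mid] / I)^a
    hot <- Tm > 26.5
    pet[hot] <- -415.85 + 32.24 * Tm[hot] - 0.43 * Tm[hot]^2
  }
  corr <- day_length_hours(series$latitude) / 12 * DAYS_IN_MONTH / 30
  pet * corr
}

#' Thornthwaite-Mather monthly climatic water balance
#'
#' Runs the standard bookkeeping: in dry months (R < PET) the accumulated
#' potential water loss NEG grows by R - PET and storage decays as
#' GW = WHC exp(NEG / WHC); in wet months storage is recharged by R - PET
#' up to WHC (overflow = EXC) and NEG is back-computed as
#' WHC ln(GW / WHC). AET equals PET in wet months and R + |ALT| in dry
#' months (never exceeding PET); DEF = PET - AET. The cycle starts after
#' the wettest month and is iterated until the storage vector converges
#' month-wise below 0.01 mm.
#'
#' When the year is arid in aggregate — sum(R - PET) < 0 while
#' WHC > sum of the positive monthly R - PET — storage can never fill, and
#' the simplified arid-case variant is used: the cycle is anchored with
#' maximum storage equal to sum (R - PET)+ instead of WHC, then the same
#' recursion runs to its fixed point. The branch taken is recorded.
#'
#' @param series a `climate_series`.
#' @param pet optional precomputed monthly PET; default
#'   [thornthwaite_pet()].
#' @return object of class `water_balance`: a 12-row data.frame with
#'   columns month, temperature, rainfall, pet, neg, gw, alt, aet, def,
#'   exc; attributes `annual` (named sums), `branch`
#'   (`"standard"`/`"pereira_arid"`), `cycles`, `whc`, `site`.
#' @export
water_balance <- function(series, pet = thornthwaite_pet(series)) {
  stopifnot(inherits(series, "climate_series"))
  R <- series$rainfall; whc <- series$whc
  diffm <- R - pet
  arid <- sum(diffm) < 0 && whc > sum(pmax(diffm, 0))
  branch <- if (arid) "pereira_arid" else "standard"
  gw_start <- if (arid) min(sum(pmax(diffm, 0)), whc) else whc
  if (gw_start <= 0) gw_start <- 1e-9       # fully rainless year

  start <- which.max(R) %% 12 + 1           # month after the wettest month
  ord <- ((start - 1 + 0:11) %% 12) + 1
  gw <- rep(gw_start, 12)
  neg <- rep(0, 12)
  exc <- rep(0, 12)
  prev_gw <- gw_start
  prev_neg <- whc * log(gw_start / whc)
  converged <- FALSE
  for (cycle in seq_len(100)) {
    gw_before <- gw
    for (m in ord) {
      if (diffm[m] < 0) {                   # dry month: exponential drawdown
        neg[m] <- prev_neg + diffm[m]
        gw[m] <- whc * exp(neg[m] / whc)
        exc[m] <- 0
      } else {                              # wet month: recharge, maybe spill
        g <- prev_gw + diffm[m]
        exc[m] <- max(0, g - whc)
        gw[m] <- min(g, whc)
        neg[m] <- if (gw[m] < whc) whc * log(gw[m] / whc) else 0
      }
      prev_gw <- gw[m]; prev_neg <- neg[m]
    }
    if (max(abs(gw - gw_before)) < 0.01 && cycle > 1) { converged <- TRUE; break }
  }
  if (!converged)
    stop("water balance failed to converge after 100 cycles; GW trace: ",
         paste(sprintf("%.2f", gw), collapse = " "))

  alt <- gw - gw[c(12, 1:11)]               # cyclic storage change
  aet <- ifelse(diffm < 0, pmin(R + pmax(-alt, 0), pet), pet)
  def <- pet - aet
  tab <- data.frame(month = 1:12, temperature = series$temperature,
                    rainfall = R, pet = pet, neg = neg, gw = gw, alt = alt,
                    aet = aet, def = def, exc = exc)
  annual <- c(rainfall = sum(R), pet = sum(pet), aet = sum(aet),
              def = sum(def), exc = sum(exc))
  structure(tab, class = c("water_balance", "data.frame"), annual = annual,
            branch = branch, cycles = cycle, whc = whc, site = series$site)
}

#' @export
print.water_balance <- function(x, ...) {
  a <- attr(x, "annual")
  cat(sprintf("water_balance (%s, %s branch): R %.0f, PET %.0f, AET %.0f, DEF %.0f, EXC %.0f mm/yr\n",
              attr(x, "site"), attr(x, "branch"), a["rainfall"], a["pet"],
              a["aet"], a["def"], a["exc"]))
  print.data.frame(round(as.data.frame(x), 1))
  invisible(x)
}

#' Write a water-balance ledger to CSV
#' @param wb a `water_balance`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_water_balance <- function(wb, path) {
  write.csv(as.data.frame(wb), path, row.names = FALSE)
  invisible(path)
}
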