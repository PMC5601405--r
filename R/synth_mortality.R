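#' Generate a synthetic all-cause life table
#'
#' Gompertz-type annual death probabilities
#' `q(x) = min(1, a * exp(b * x))`, monotone non-decreasing in age, with
#' mandatory closure (`q = 1`) at `max_age`. This is a synthetic
#' stand-in for national life tables, which are not publicly deposited
#' with the model; see [calibrate_gompertz()] for the default
#' calibration.
#'
#' @param a Baseline hazard level, >= 0.
#' @param b Exponential age slope, >= 0.
#' @param age_start First tabulated age (default 35).
#' @param max_age Closing age (default 100).
#' @return A data.frame of class `life_table` with columns `age`, `qx`.
#' @examples
#' lt <- generate_life_table(1.296e-5, 0.10)
#' @export
generate_life_table <- function(a = 1.296e-5, b = 0.10,
                                age_start = 35, max_age = 100) {
  if (a < 0 || b < 0) stop("Gompertz parameters must be non-negative", call. = FALSE)
  stopifnot(max_age > age_start)
  age <- age_start:max_age
  qx <- pmin(1, a * exp(b * age))
  qx[length(qx)] <- 1  # closure
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Generate a synthetic stage-specific breast-cancer mortality table
#'
#' Annual breast-cancer death probabilities for post-chemotherapy years
#' 1-5, `p(stage, year) = stage_base[stage] * decay^(year - 1)`, a
#' synthetic stand-in for registry data. Stage ordering IV >= III >= II
#' must hold in `stage_base` and is then preserved for every year.
#' Defaults correspond to roughly 93/82/42% five-year cause-specific
#' survival for stages II/III/IV.
#'
#' @param stage_base Named year-1 probabilities `c(II=, III=, IV=)`.
#' @param annual_decay Geometric decay per year, in (0, 1].
#' @param years Number of post-chemotherapy years (default 5).
#' @return A data.frame of class `bc_mortality` with columns `stage`,
#'   `year`, `qx`.
#' @export
generate_bc_mortality <- function(stage_base = c(II = 0.02, III = 0.06, IV = 0.25),
                                  annual_decay = 0.8, years = 5) {
  stopifnot(length(stage_base) == 3, all(c("II", "III", "IV") %in% names(stage_base)),
            annual_decay > 0, annual_decay <= 1,
            all(stage_base >= 0), all(stage_base <= 1))
  if (stage_base[["IV"]] < stage_base[["III"]] ||
      stage_base[["III"]] < stage_base[["II"]])
    stop("stage ordering violated: need IV >= III >= II in stage_base",
         call. = FALSE)
  g <- expand.grid(year = seq_len(years), stage = c("II", "III", "IV"),
                   stringsAsFactors = FALSE)
  qx <- stage_base[g$stage] * annual_decay^(g$year - 1)
  structure(data.frame(stage = g$stage, year = g$year, qx = unname(qx)),
            class = c("bc_mortality", "data.frame"))
}

#' Calibrate Gompertz parameters to a target residual life expectancy
#'
#' Bisection on `a` at fixed slope `b` so that the discrete residual
#' life expectancy at `age` matches `target_le`. The package defaults
#' (`a = 1.296e-5`, `b = 0.10`) were produced by this routine for a
#' residual life expectancy of 26 years at age 59, a plausible value
#' for women of that age in a western European population; no claim is
#' made of matching any specific national table.
#'
#' @param target_le Target residual life expectancy in years.
#' @param b Fixed exponential slope.
#' @param age Reference age.
#' @param max_age Horizon.
#' @return List with elements `a`, `b`, `le`.
#' @export
calibrate_gompertz <- function(target_le = 26, b = 0.10, age = 59, max_age = 100) {
  f <- function(a) life_expectancy(generate_life_table(a, b, 35, max_age), age) - target_le
  lo <- 1e-10; hi <- 1e-2
  if (f(lo) < 0 || f(hi) > 0) stop("target life expectancy out of reach", call. = FALSE)
  for (i in 1:200) { mid <- sqrt(lo * hi); if (f(mid) > 0) lo <- mid else hi <- mid }
  a <- sqrt(lo * hi)
  list(a = a, b = b, le = f(a) + target_le)
}

#' Residual life expectancy from a life table
#'
#' Discrete expectation counting survivors at the end of each year:
#' `sum_t prod_{s<=t} (1 - q(age + s - 1))`.
#'
#' @param life_table A `life_table`.
#' @param age Starting age.
#' @return Residual life expectancy in years.
#' @export
life_expectancy <- function(life_table, age) {
  q <- life_table_q(life_table, age, max(life_table$age))
  sum(cumprod(1 - q))
}

# annual q for ages [age_from, age_to - 1]; errors on gaps
life_table_q <- function(life_table, age_from, age_to) {
  ages <- age_from:(age_to - 1)
  idx <- match(ages, life_table$age)
  if (anyNA(idx))
    stop("life table is missing ages: ",
         paste(ages[is.na(idx)], collapse = ", "), call. = FALSE)
  life_table$qx[idx]
}

# stage-mix-weighted breast-cancer q for year t (0 beyond the table)
bc_mix_q <- function(bc_table, year, stage_mix) {
  if (year > max(bc_table$year)) return(0)
  rows <- bc_table[bc_table$year == year, ]
  idx <- match(names(stage_mix), rows$stage)
  if (anyNA(idx)) stop("breast-cancer mortality table is missing stages: ",
                       paste(names(stage_mix)[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  sum(stage_mix * rows$qx[idx])
}

## -- CSV I/O -----------------------------------------------------------

#' Read / write mortality tables as CSV
#'
#' Plain CSV with header: `age,qx` for life tables, `stage,year,qx` for
#' breast-cancer mortality. Reading validates probabilities and, for
#' life tables, errors on missing ages within the covered range.
#'
#' @param path File path.
#' @param table A `life_table` / `bc_mortality`.
#' @return The table (readers), invisibly the path (writers).
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table CSV must have columns age, qx", call. = FALSE)
  df <- df[order(df$age), c("age", "qx")]
  gaps <- setdiff(seq(min(df$age), max(df$age)), df$age)
  if (length(gaps))
    stop("life table has gaps at ages: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  if (any(df$qx < 0 | df$qx > 1))
    stop("life table qx outside [0, 1]", call. = FALSE)
  structure(df, class = c("life_table", "data.frame"), row.names = seq_len(nrow(df)))
}

#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_life_table
#' @export
read_bc_mortality <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("stage", "year", "qx") %in% names(df)))
    stop("breast-cancer mortality CSV must have columns stage, year, qx",
         call. = FALSE)
  if (any(df$qx < 0 | df$qx > 1))
    stop("breast-cancer mortality qx outside [0, 1]", call. = FALSE)
  df <- df[order(df$stage, df$year), c("stage", "year", "qx")]
  structure(df, class = c("bc_mortality", "data.frame"),
            row.names = seq_len(nrow(df)))
}

#' @rdname read_life_table
#' @export
write_bc_mortality <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("stage", "year", "qx")], path,
                   row.names = FALSE)
  invisible(path)
}
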