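#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Conversion factor mmol/L -> mg/dL (glucose molar mass 180.182 g/mol).
MMOL_TO_MGDL <- 18.0182

# Reportable CGM range used when clipping simulated traces, mg/dL.
CGM_CLIP_RANGE <- c(40, 400)

MINUTES_PER_DAY <- 1440L

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# All analyses run in naive local clinic time; POSIXct in UTC stands in for
# a timezone-free wall clock (no DST adjustment is ever applied).
as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::force_tz(x, "UTC"))
  }
  if (inherits(x, "Date")) {
    return(lubridate::force_tz(as.POSIXct(x, tz = "UTC"), "UTC"))
  }
  out <- lubridate::ymd_hms(x, tz = "UTC", truncated = 3, quiet = TRUE)
  out
}

as_naive_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXct")) return(lubridate::as_date(x))
  lubridate::as_date(x)
}

fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
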