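# Internal helpers shared across modules.

# Producer classes in increasing order of production.
PRODUCER_LEVELS <- c("NP", "WP", "MP", "SP")

# Condition factor families.
FACTOR_LEVELS <- c("baseline", "temperature", "nacl", "ph")

READING_COLS <- c("plate_id", "well", "channel", "timepoint_h", "stage",
                  "absorbance")
LAYOUT_COLS <- c("plate_id", "well", "role", "isolate_id", "factor", "level",
                 "bio_rep", "tech_rep")

STAGES <- c("growth_endpoint", "rz_baseline", "rz_final")
CHANNELS <- c("OD570", "OD600")
ROLES <- c("sample", "sterility_control", "reference_control")

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards, so no global state leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical one-string label for a condition, e.g. "baseline", "ph:7".
condition_label <- function(factor, level) {
  ifelse(is.na(level) | factor == "baseline",
         as.character(factor),
         paste0(factor, ":", format(level, trim = TRUE)))
}

is_valid_well <- function(well) {
  grepl("^[A-H](1[0-2]|[1-9])$", well)
}

# sample SD with the convention sd = 0 for a single observation
sd0 <- function(x) if (length(x) <= 1) 0 else stats::sd(x)

producer_factor <- function(x) {
  factor(as.character(x), levels = PRODUCER_LEVELS, ordered = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
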