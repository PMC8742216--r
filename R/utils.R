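# Internal time helpers.  All timestamps are normalized to POSIXct in UTC
# (a single timezone-naive convention); durations are handled in seconds.

.HOUR <- 3600
.DAY <- 86400

.parse_time <- function(x) {
    if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x),
                                                  origin = "1970-01-01",
                                                  tz = "UTC"))
    if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
    x <- as.character(x)
    # element-wise fallback: a vector mixing "T"-separated, space-separated
    # and date-only stamps must not be truncated wholesale
    out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
                      tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
        na <- is.na(out) & !is.na(x)
        if (!any(na)) break
        out[na] <- as.POSIXct(strptime(x[na], fmt, tz = "UTC"), tz = "UTC")
    }
    na <- is.na(out) & !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    if (any(na))
        out[na] <- as.POSIXct(strptime(x[na], "%Y-%m-%d", tz = "UTC"),
                              tz = "UTC")
    out
}

.fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Deterministic child seed derived from a user seed and a stream label;
# kept below 2^31 - 1.
.child_seed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((as.numeric(seed) * 1103515245 + h * 12345) %% 2147483629)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
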