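# Internal helpers shared across modules.

GEAR_LABELS <- c("OTB", "PTM", "TBB", "PS", "OTHER")

#' Gear labels used throughout the package
#'
#' The closed five-value set of gear classes: bottom otter trawl (`OTB`),
#' pelagic pair trawl (`PTM`), beam trawl (`TBB`), purse seine (`PS`) and
#' everything else (`OTHER`).
#'
#' @return Character vector of the five gear labels.
#' @export
gear_labels <- function() GEAR_LABELS

check_gear <- function(gear) {
  if (!(is.character(gear) && length(gear) == 1L && gear %in% GEAR_LABELS)) {
    stop("unknown gear label: ", paste(gear, collapse = ", "),
         " (must be one of ", paste(GEAR_LABELS, collapse = ", "), ")",
         call. = FALSE)
  }
  gear
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Linear month index (0-based within an arbitrary origin).
ym_index <- function(year, month) year * 12L + (month - 1L)

# Inverse of ym_index.
ym_from_index <- function(idx) {
  data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

# Sequence of (year, month) rows starting at `start = c(year, month)`.
month_seq <- function(start, n) {
  idx <- ym_index(as.integer(start[1]), as.integer(start[2])) + seq_len(n) - 1L
  ym_from_index(idx)
}

# Polynomial rolling hash of a character scalar, as 8 hex digits. Used to
# give run reports a stable configuration fingerprint without external deps.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
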