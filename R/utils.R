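# Shared internal helpers: PCRE matching with named captures, overlap
# resolution, percentage formatting. Offsets are 0-based, half-open
# everywhere in this package; R's 1-based substr() is confined to here.

# All match tables carry 0-based half-open [start, end) character offsets.
re_match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  empty <- tibble::tibble(
    start = integer(), end = integer(), match = character(),
    ref = character(), pos = character(), alt = character()
  )
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  cn <- attr(m, "capture.names")
  grp <- function(name) {
    if (is.null(cn) || !name %in% cn) return(rep(NA_character_, length(starts)))
    i <- which(cn == name)[1L]
    s <- cs[, i]
    l <- cl[, i]
    out <- substring(text, s, s + l - 1L)
    out[s <= 0L | l <= 0L] <- NA_character_
    out
  }
  tibble::tibble(
    start = starts - 1L,
    end = starts + lens - 1L,
    match = substring(text, starts, starts + lens - 1L),
    ref = grp("ref"), pos = grp("pos"), alt = grp("alt")
  )
}

# Greedy longest-match-first selection of non-overlapping spans; ties by
# leftmost start, then by `priority` (lower wins, i.e. pattern order).
resolve_overlaps <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- dplyr::arrange(cand, dplyr::desc(.data$end - .data$start),
                         .data$start, .data$priority)
  keep <- logical(nrow(cand))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    clash <- any(occupied[, 1] < e & s < occupied[, 2])
    if (!clash) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  dplyr::arrange(cand[keep, , drop = FALSE], .data$start)
}

# 0-based half-open slice of a string.
slice0 <- function(text, start, end) substring(text, start + 1L, end)

# Truncate (not round) to `digits` decimals; the printed precision never
# overstates the computed fraction.
trunc_dec <- function(x, digits = 2L) floor(x * 10^digits + 1e-9) / 10^digits

format_pct <- function(x, digits = 2L) {
  ifelse(is.na(x), "undefined",
         sprintf(paste0("%.", digits, "f%%"), trunc_dec(x, digits)))
}

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

canonical_regex <- "^[ACDEFGHIKLMNPQRSTVWY*][1-9][0-9]*[ACDEFGHIKLMNPQRSTVWY*]$"

mention_cols <- function() {
  tibble::tibble(
    doc_id = character(), sentence_id = integer(),
    start = integer(), end = integer(), raw_text = character(),
    source_block = character(), mention_kind = character(),
    pattern_id = character(),
    ref = character(), pos = integer(), alt = character()
  )
}
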