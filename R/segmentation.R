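# Partition alignment columns into structurally conserved (SCR) and
# structurally variable (SVR) regions.

#' Segment alignment columns into SCRs and SVRs
#'
#' Columns whose superposed CA-CA distance exceeds `scr_max` -- or is
#' undefined (gap columns) -- are SVR candidates.  Maximal candidate runs of
#' at least `svr_min_len` columns become SVRs; shorter runs are absorbed
#' into the surrounding SCR.  Runs touching the first or last column are
#' flagged terminal.
#'
#' @param distances per-column CA-CA distances in Angstrom (NA at gaps), from
#'   [column_distances()].
#' @param scr_max SCR distance threshold in Angstrom (default 3.0).
#' @param svr_min_len minimum SVR run length in columns (default 3).
#' @return A `region_set`: data.frame with columns `kind` ("SCR"/"SVR"),
#'   `start`, `end` (1-based, closed), `terminal` (logical) and `svr_id`
#'   (NA for SCRs), tiling the columns exactly.
#' @export
segment_regions <- function(distances, scr_max = 3.0, svr_min_len = 3L) {
  n <- length(distances)
  if (n < 1L) stop_pbsvr("pbsvr_empty_alignment", "no columns to segment")
  cand <- is.na(distances) | distances > scr_max
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_svr <- r$values & r$lengths >= svr_min_len
  # everything not an SVR run is SCR; merge adjacent SCR stretches
  kind <- ifelse(is_svr, "SVR", "SCR")
  i <- 1L
  while (i < length(kind)) {
    if (kind[i] == "SCR" && kind[i + 1L] == "SCR") {
      ends[i] <- ends[i + 1L]
      kind <- kind[-(i + 1L)]; starts <- starts[-(i + 1L)]
      ends <- ends[-(i + 1L)]
    } else i <- i + 1L
  }
  out <- data.frame(kind = kind, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  out$terminal <- out$kind == "SVR" & (out$start == 1L | out$end == n)
  out$svr_id <- NA_integer_
  out$svr_id[out$kind == "SVR"] <- seq_len(sum(out$kind == "SVR"))
  out$excluded <- FALSE
  class(out) <- c("region_set", "data.frame")
  out
}

#' Flag terminal SVRs as excluded from assessment
#'
#' Terminal SVRs keep their interval but are marked excluded: the two
#' unassigned PB positions at each end of a PB sequence make their PB
#' realignment unreliable, so they are not assessed.
#'
#' @param regions a `region_set` from [segment_regions()].
#' @return The `region_set` with `excluded` set for terminal SVRs.
#' @export
exclude_terminal <- function(regions) {
  regions$excluded <- regions$kind == "SVR" & regions$terminal
  regions
}
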