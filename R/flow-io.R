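#' Write an event table as an FCS 3.0 file
#'
#' Writes list-mode data in FCS 3.0 format: list mode (`$MODE/L`),
#' single-precision floats (`$DATATYPE/F`), little-endian
#' (`$BYTEORD/1,2,3,4`), with parameters named `FSC-H`, `SSC-H` and
#' `FL1-A`. Values are stored as 32-bit floats, so a round trip preserves
#' them to single precision (about 7 significant digits). A latent
#' `phase` column, if present, is not part of the FCS standard and is
#' dropped.
#'
#' @param events An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  dat <- as.matrix(events[, c("fsc", "ssc", "fl_a")])
  n <- nrow(dat)
  pnames <- c("FSC-H", "SSC-H", "FL1-A")
  pr <- vapply(seq_len(3),
               function(j) max(1024, 2^ceiling(log2(max(dat[, j], 1)))),
               numeric(1))
  d <- "|"
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          # fixed-width so offsets do not change once filled in
          "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0),
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = "3", "$TOT" = as.character(n))
  for (j in 1:3) {
    kw[sprintf("$P%dN", j)] <- pnames[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- as.character(pr[j])
  }
  build_text <- function(kw) {
    paste0(d, paste0(names(kw), d, unname(kw), d, collapse = ""))
  }
  text_start <- 58L   # immediately after the 58-byte header
  txt <- build_text(kw)
  data_start <- text_start + nchar(txt, type = "bytes")
  data_end <- data_start + 4L * 3L * n - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  txt <- build_text(kw)
  stopifnot(text_start + nchar(txt, type = "bytes") == data_start)

  hdr <- paste0("FCS3.0    ",
                sprintf("%8d", text_start),
                sprintf("%8d", data_start - 1L),
                sprintf("%8d", data_start),
                sprintf("%8d", data_end),
                sprintf("%8d", 0L), sprintf("%8d", 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, txt), con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(dat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0 file into an event table
#'
#' Parses the header offsets and TEXT segment of an FCS 3.0 (or 3.1)
#' file and reads list-mode float data. The parameters `FSC-H`, `SSC-H`
#' and `FL1-A` must be present; a missing parameter raises a format
#' error naming the field.
#'
#' @param path Path to an FCS file.
#' @return An [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path))
    stop("read_fcs: file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 10, useBytes = TRUE)
  if (!grepl("^FCS3\\.", magic))
    stop("read_fcs: not an FCS 3.x file (header '", trimws(magic), "')",
         call. = FALSE)
  off <- suppressWarnings(as.integer(
    vapply(1:6, function(i) trimws(readChar(con, 8, useBytes = TRUE)),
           character(1))))
  if (any(is.na(off[1:2])))
    stop("read_fcs: malformed header offsets", call. = FALSE)
  seek(con, off[1])
  txt <- readChar(con, off[2] - off[1] + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) %% 2 != 0)
    parts <- parts[seq_len(2 * (length(parts) %/% 2))]
  kw <- stats::setNames(trimws(parts[seq(2, length(parts), 2)]),
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(k) {
    if (is.na(kw[k]) || is.null(kw[k]))
      stop("read_fcs: required keyword ", k, " missing", call. = FALSE)
    unname(kw[k])
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("read_fcs: unsupported $DATATYPE '", dtype, "' (need F or D)",
         call. = FALSE)
  endian <- if (grepl("^1", need("$BYTEORD"))) "little" else "big"
  dbeg <- off[3]
  dend <- off[4]
  if (is.na(dbeg) || dbeg == 0) dbeg <- as.integer(need("$BEGINDATA"))
  if (is.na(dend) || dend == 0) dend <- as.integer(need("$ENDDATA"))
  pn <- vapply(seq_len(npar),
               function(j) unname(kw[sprintf("$P%dN", j)]), character(1))
  want <- c(fsc = "FSC-H", ssc = "SSC-H", fl_a = "FL1-A")
  idx <- match(want, pn)
  if (any(is.na(idx)))
    stop("read_fcs: required parameter ", want[which(is.na(idx))[1]],
         " missing from file", call. = FALSE)
  seek(con, dbeg)
  sz <- if (dtype == "F") 4L else 8L
  vals <- readBin(con, "numeric", n = npar * ntot, size = sz,
                  endian = endian)
  m <- matrix(vals, ncol = npar, byrow = TRUE)
  event_table(fsc = m[, idx[1]], ssc = m[, idx[2]], fl_a = m[, idx[3]])
}

#' Read / write event tables as CSV
#'
#' CSV columns: `fsc`, `ssc`, `fl_a` and optionally `phase`.
#'
#' @param events An [event_table()].
#' @param path File path.
#' @return `read_events_csv` returns an [event_table()];
#'   `write_events_csv` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("fsc", "ssc", "fl_a"))
    if (is.null(df[[col]]))
      stop("read_events_csv: required column ", col, " missing",
           call. = FALSE)
  event_table(fsc = df$fsc, ssc = df$ssc, fl_a = df$fl_a,
              phase = df$phase)
}

#' Density-based debris autogate
#'
#' Reproduces the asymmetric debris gate used in screen-style DNA-content
#' analysis: particulate non-yeast events have both very low forward
#' scatter and low fluorescence, while intact cells form a contiguous
#' high-density region with FSC near ~100 and FL1-A near ~300 on the
#' 0--1023 scale. The gate builds a 2-D kernel density map over
#' (FSC, FL1-A), thresholds it at a fraction of the modal density, labels
#' the connected above-threshold regions, and discards every region whose
#' density-weighted centroid sits below both `fsc_floor` and `fl_floor`
#' (the low-FSC AND low-FL corner). Events in sub-threshold cells are
#' assigned to the nearest above-threshold region, so the retained set is
#' the full contiguous cell population rather than only its dense core.
#'
#' @param events An [event_table()] with at least 100 events.
#' @param grid Density grid resolution per axis.
#' @param threshold_frac Density threshold as a fraction of the modal
#'   density; regions above it are candidate populations.
#' @param fsc_floor,fl_floor A region is called debris only if its
#'   centroid lies below both floors (instrument units).
#' @return A `gate_result`: list with `retained` (an [event_table()]),
#'   `fraction_retained`, and `gate_descriptor` (threshold, floors and
#'   per-region summary; serialisable with [write_gate_json()]).
#' @examples
#' ev <- simulate_events(wt_population_spec(f_debris = 0.09, seed = 1))
#' g <- autogate(ev)
#' g$fraction_retained   # ~0.91
#' @export
autogate <- function(events, grid = 128L, threshold_frac = 0.02,
                     fsc_floor = 50, fl_floor = 150) {
  stopifnot(inherits(events, "event_table"))
  n <- nrow(events)
  if (n < 100)
    stop("autogate: need at least 100 events", call. = FALSE)
  x <- events$fsc
  y <- events$fl_a
  pad <- function(v) {
    r <- range(v)
    w <- max(diff(r), 1e-6)
    c(r[1] - 0.05 * w, r[2] + 0.05 * w)
  }
  bw <- function(v) {
    h <- MASS::bandwidth.nrd(v)
    if (!is.finite(h) || h <= 0) h <- max(diff(range(v)) / 25, 1e-3)
    h
  }
  lims <- c(pad(x), pad(y))
  kd <- MASS::kde2d(x, y, h = c(bw(x), bw(y)), n = grid, lims = lims)
  z <- kd$z
  mask <- z >= threshold_frac * max(z)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(z))

  # density-weighted centroid of each labelled region, in data units
  labs <- sort(unique(lab[lab > 0]))
  cx <- matrix(rep(kd$x, grid), nrow = grid)
  cy <- matrix(rep(kd$y, each = grid), nrow = grid)
  comp <- do.call(rbind, lapply(labs, function(l) {
    w <- z * (lab == l)
    s <- sum(w)
    data.frame(label = l, fsc = sum(cx * w) / s, fl_a = sum(cy * w) / s,
               peak_density = max(z[lab == l]))
  }))
  comp$debris <- comp$fsc < fsc_floor & comp$fl_a < fl_floor
  mode_label <- lab[which.max(z)]
  if (comp$debris[comp$label == mode_label])
    stop("autogate: degenerate gate - the modal population lies in the ",
         "low-FSC, low-FL debris region", call. = FALSE)
  kept <- comp$label[!comp$debris]
  if (!length(kept))
    stop("autogate: degenerate gate - all events excluded", call. = FALSE)

  # propagate labels into sub-threshold cells (nearest labelled region)
  full <- propagate_labels(lab)

  ix <- pmin(pmax(findInterval(x, kd$x, rightmost.closed = TRUE), 1L), grid)
  iy <- pmin(pmax(findInterval(y, kd$y, rightmost.closed = TRUE), 1L), grid)
  ev_lab <- full[cbind(ix, iy)]
  keep <- ev_lab %in% kept
  if (!any(keep))
    stop("autogate: degenerate gate - all events excluded", call. = FALSE)

  retained <- events[keep, , drop = FALSE]
  class(retained) <- class(events)
  attr(retained, "true_pct_g1") <- attr(events, "true_pct_g1")
  structure(list(
    retained = retained,
    fraction_retained = sum(keep) / n,
    gate_descriptor = list(
      method = "density-mode autogate",
      grid = grid, threshold_frac = threshold_frac,
      threshold_density = threshold_frac * max(z),
      fsc_floor = fsc_floor, fl_floor = fl_floor,
      kept_labels = kept, components = comp
    )
  ), class = "gate_result")
}

# nearest-region label propagation over the density grid (multi-source
# dilation with 4-neighbourhoods; deterministic tie-break by shift order)
propagate_labels <- function(lab) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  while (any(lab == 0L)) {
    grew <- FALSE
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- matrix(0L, nr, nc)
      ri <- seq_len(nr) - sh[1]
      ci <- seq_len(nc) - sh[2]
      ok_r <- ri >= 1 & ri <= nr
      ok_c <- ci >= 1 & ci <= nc
      nb[ok_r, ok_c] <- lab[ri[ok_r], ci[ok_c]]
      fill <- lab == 0L & nb > 0L
      if (any(fill)) {
        lab[fill] <- nb[fill]
        grew <- TRUE
      }
    }
    if (!grew) break   # isolated all-zero grid (cannot happen with a mode)
  }
  lab
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Autogate: retained %d / %d events (%.1f%%)\n",
              nrow(x$retained),
              round(nrow(x$retained) / x$fraction_retained),
              100 * x$fraction_retained))
  invisible(x)
}

#' Serialise a gate descriptor to JSON
#'
#' @param gate A `gate_result` from [autogate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_json <- function(gate, path) {
  stopifnot(inherits(gate, "gate_result"))
  desc <- gate$gate_descriptor
  desc$fraction_retained <- gate$fraction_retained
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Bin gated fluorescence into a DNA-content histogram
#'
#' Bins the `fl_a` channel into `n_channels` equal-width, left-closed /
#' right-open channels spanning `range`. Events outside `range` are
#' dropped (the totals then reflect in-range events only).
#'
#' @param events An [event_table()] (normally the gated population).
#' @param n_channels Number of channels (default 1024, linear scale).
#' @param range Fluorescence range covered by the channels.
#' @return A [dna_histogram()].
#' @export
bin_histogram <- function(events, n_channels = 1024L, range = c(0, 1024)) {
  stopifnot(inherits(events, "event_table"))
  if (n_channels <= 1)
    stop("bin_histogram: n_channels must exceed 1", call. = FALSE)
  width <- (range[2] - range[1]) / n_channels
  idx <- floor((events$fl_a - range[1]) / width) + 1
  idx <- idx[idx >= 1 & idx <= n_channels]
  counts <- tabulate(idx, nbins = n_channels)
  h <- dna_histogram(counts, channel_width = width, origin = range[1])
  attr(h, "true_pct_g1") <- attr(events, "true_pct_g1")
  h
}
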