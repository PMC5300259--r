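#' @keywords internal
"_PACKAGE"

## Unit conventions used throughout: time ms, current pA (inward negative),
## concentrations uM except zinc (nM, nominal free), potential mV,
## conductance pS. Summary tables report current magnitudes as positive.

EPOCH_FIELDS <- c("start", "duration", "glutamate", "glycine", "mk801",
                  "mtsea", "pH", "zinc", "magnesium", "holding_potential")

COMPOSITIONS <- c("WT2A", "2A-D731N", "2A/2A", "D731N/2A", "D731N/D731N",
                  "A652C-WT2A", "A652C-2A-D731N")

#' Define one solution-exchange epoch
#'
#' An epoch is one period during which the bath (or theta-tube barrel)
#' solution has a fixed nominal composition and the cell is held at a fixed
#' potential. Concentrations are micromolar except zinc (nanomolar nominal
#' free Zn2+ in tricine-buffered solutions).
#'
#' @param start Epoch start time (ms).
#' @param duration Epoch duration (ms), > 0.
#' @param glutamate,glycine,mk801,mtsea Concentrations (uM), >= 0.
#' @param pH Solution pH in [5.5, 9].
#' @param zinc Nominal free zinc (nM), >= 0.
#' @param magnesium Magnesium (uM), >= 0.
#' @param holding_potential Command potential (mV).
#' @return A one-row data.frame with the epoch fields.
#' @export
epoch <- function(start, duration, glutamate = 0, glycine = 0, mk801 = 0,
                  mtsea = 0, pH = 7.4, zinc = 0, magnesium = 0,
                  holding_potential = -40) {
  e <- data.frame(start = start, duration = duration, glutamate = glutamate,
                  glycine = glycine, mk801 = mk801, mtsea = mtsea, pH = pH,
                  zinc = zinc, magnesium = magnesium,
                  holding_potential = holding_potential)
  validate_epochs(e)
  e
}

validate_epochs <- function(epochs) {
  stopifnot(is.data.frame(epochs), nrow(epochs) >= 1)
  missing <- setdiff(EPOCH_FIELDS, names(epochs))
  if (length(missing) > 0)
    stop("epoch table missing field(s): ", paste(missing, collapse = ", "))
  if (any(epochs$duration <= 0)) stop("epoch duration must be > 0")
  conc <- c("glutamate", "glycine", "mk801", "mtsea", "zinc", "magnesium")
  for (f in conc)
    if (any(epochs[[f]] < 0)) stop("negative concentration in field '", f, "'")
  if (any(epochs$pH < 5.5 | epochs$pH > 9.0))
    stop("pH outside the supported range [5.5, 9.0]")
  if (nrow(epochs) > 1) {
    ends <- epochs$start + epochs$duration
    gaps <- abs(epochs$start[-1] - ends[-nrow(epochs)])
    if (any(gaps > 1e-9 * pmax(1, abs(ends[-nrow(epochs)]))))
      stop("epochs must be contiguous and non-overlapping")
  }
  invisible(epochs)
}

#' Assemble a solution-exchange protocol
#'
#' @param epochs A data.frame of epochs (rows from [epoch()], rbind-ed), in
#'   chronological order, contiguous and non-overlapping.
#' @param exchange_tau First-order solution-exchange time constant (ms). The
#'   default 0.5 ms reflects fast theta-tube perfusion; oocyte bath exchange
#'   is far slower (use ~2000 ms).
#' @param label Free-text protocol label.
#' @return An object of class `nmda_protocol`.
#' @export
protocol <- function(epochs, exchange_tau = 0.5, label = "") {
  validate_epochs(epochs)
  if (exchange_tau < 0) stop("exchange_tau must be >= 0")
  if (exchange_tau >= min(epochs$duration))
    stop("exchange_tau must be shorter than the shortest epoch")
  structure(list(epochs = epochs, exchange_tau = exchange_tau, label = label),
            class = "nmda_protocol")
}

protocol_end <- function(protocol) {
  e <- protocol$epochs
  e$start[nrow(e)] + e$duration[nrow(e)]
}

#' Per-cell metadata
#'
#' @param cell_id Cell identifier.
#' @param preparation `"oocyte"` (TEVC) or `"HEK"` (whole-cell patch).
#' @param composition Receptor composition label: "WT2A", "2A-D731N",
#'   "2A/2A", "D731N/2A", "D731N/D731N", or the GluN1(A652C)-coexpressed
#'   variants "A652C-WT2A", "A652C-2A-D731N".
#' @param capacitance Whole-cell capacitance (pF); required for HEK cells,
#'   must be `NA` for oocytes (TEVC currents are not normalized).
#' @param holding_potential_default Default command potential (mV).
#' @return An object of class `nmda_cell`.
#' @export
cell_meta <- function(cell_id, preparation = c("oocyte", "HEK"),
                      composition = "WT2A", capacitance = NA_real_,
                      holding_potential_default = -40) {
  preparation <- match.arg(preparation)
  if (!composition %in% COMPOSITIONS)
    stop("unknown composition label '", composition, "'")
  if (preparation == "HEK") {
    if (is.na(capacitance) || capacitance <= 0)
      stop("HEK cells require capacitance > 0 (pF)")
  } else if (!is.na(capacitance)) {
    stop("capacitance must be absent (NA) for oocytes")
  }
  structure(list(cell_id = as.character(cell_id), preparation = preparation,
                 composition = composition, capacitance = capacitance,
                 holding_potential_default = holding_potential_default),
            class = "nmda_cell")
}

#' Construct a voltage-clamp trace
#'
#' @param time Uniform time grid (ms) spanning the protocol.
#' @param current Membrane current (pA) at each time point; inward negative.
#' @param protocol An [protocol()] object.
#' @param cell A [cell_meta()] object.
#' @param ground_truth Optional generating kinetic model (synthetic traces).
#' @return An object of class `nmda_trace`.
#' @export
new_trace <- function(time, current, protocol, cell, ground_truth = NULL) {
  if (length(time) != length(current))
    stop("time and current must have equal length")
  if (length(time) < 2) stop("trace needs at least two samples")
  dt <- diff(time)
  si <- dt[1]
  if (si <= 0 || any(abs(dt - si) > 1e-6 * si))
    stop("time grid must be uniform with positive step")
  if (!all(is.finite(current))) stop("current must be finite everywhere")
  if (!inherits(protocol, "nmda_protocol")) stop("protocol must be an nmda_protocol")
  if (!inherits(cell, "nmda_cell")) stop("cell must be an nmda_cell")
  span_lo <- protocol$epochs$start[1]
  span_hi <- protocol_end(protocol)
  if (time[1] > span_lo + si/2 || time[length(time)] < span_hi - si)
    stop("time grid must span the protocol")
  structure(list(time = time, current = current, sample_interval = si,
                 protocol = protocol, cell = cell, ground_truth = ground_truth),
            class = "nmda_trace")
}

#' @export
print.nmda_trace <- function(x, ...) {
  cat(sprintf("<nmda_trace> cell %s (%s, %s): %d samples @ %.4g ms, %d epoch(s)\n",
              x$cell$cell_id, x$cell$preparation, x$cell$composition,
              length(x$time), x$sample_interval, nrow(x$protocol$epochs)))
  invisible(x)
}

meta_path <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.json")

#' Write a trace to the CSV + JSON-sidecar interchange format
#'
#' The trace samples go to `path` as a two-column CSV (`time_ms,current_pA`);
#' cell metadata, the protocol, the sample interval and any ground-truth model
#' go to `<path without .csv>.meta.json`.
#'
#' @param trace An `nmda_trace`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nmda_trace"))
  if (!all(is.finite(trace$current))) stop("refusing to write non-finite current")
  df <- data.frame(time_ms = format_num(trace$time),
                   current_pA = format_num(trace$current))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    cell = unclass(trace$cell),
    protocol = list(epochs = trace$protocol$epochs,
                    exchange_tau = trace$protocol$exchange_tau,
                    label = trace$protocol$label),
    sample_interval = trace$sample_interval,
    ground_truth = if (!is.null(trace$ground_truth)) unclass(trace$ground_truth)
  )
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a trace from the CSV + JSON-sidecar interchange format
#'
#' @param path Path to the CSV written by [write_trace()].
#' @return An `nmda_trace` with all invariants checked.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("sidecar metadata not found: ", mp)
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "current_pA") %in% names(df)))
    stop("trace CSV must have columns time_ms,current_pA")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in c("cell", "protocol", "sample_interval"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'")
  cm <- meta$cell
  cell <- cell_meta(cm$cell_id, cm$preparation, cm$composition,
                    if (is.null(cm$capacitance) || is.na(cm$capacitance))
                      NA_real_ else cm$capacitance,
                    cm$holding_potential_default)
  ep <- as.data.frame(meta$protocol$epochs)
  prot <- protocol(ep, meta$protocol$exchange_tau,
                   if (is.null(meta$protocol$label)) "" else meta$protocol$label)
  gt <- if (!is.null(meta$ground_truth)) do.call(kinetic_model, as.list(meta$ground_truth))
  tr <- new_trace(df$time_ms, df$current_pA, prot, cell, ground_truth = gt)
  si_file <- meta$sample_interval
  if (abs(tr$sample_interval - si_file) > 1e-6 * si_file)
    stop("sidecar sample_interval disagrees with the CSV time grid")
  tr
}

#' Subtract the holding-current baseline
#'
#' Shifts the whole trace by a constant so that the mean current over
#' `window` (which must lie in an agonist-free stretch of the protocol) is
#' zero. Idempotent.
#'
#' @param trace An `nmda_trace`.
#' @param window Numeric length-2 vector `c(t0, t1)` in ms.
#' @return The baseline-corrected trace.
#' @export
baseline_correct <- function(trace, window) {
  stopifnot(inherits(trace, "nmda_trace"), length(window) == 2, window[2] > window[1])
  if (window[1] < trace$time[1] || window[2] > trace$time[length(trace$time)])
    stop("baseline window lies outside the trace")
  ep <- trace$protocol$epochs
  covering <- which(ep$start <= window[1] + 1e-9 &
                    (ep$start + ep$duration) >= window[2] - 1e-9)
  if (length(covering) == 0 || any(ep$glutamate[covering] > 0))
    stop("baseline window must lie inside a zero-agonist epoch")
  idx <- trace$time >= window[1] & trace$time <= window[2]
  trace$current <- trace$current - mean(trace$current[idx])
  trace
}

#' Measure the response within one epoch
#'
#' `steady` mode averages the last 20% of the epoch; `peak` mode returns the
#' signed extremum after the solution-exchange dead time (3 x exchange_tau
#' past the epoch start). Both return signed current: inward responses are
#' negative.
#'
#' @param trace A baseline-corrected `nmda_trace`.
#' @param epoch_index 1-based epoch index.
#' @param mode `"steady"` or `"peak"`.
#' @return Signed current (pA).
#' @export
epoch_response <- function(trace, epoch_index, mode = c("steady", "peak")) {
  mode <- match.arg(mode)
  ep <- trace$protocol$epochs
  if (epoch_index < 1 || epoch_index > nrow(ep)) stop("no such epoch")
  t0 <- ep$start[epoch_index]
  t1 <- t0 + ep$duration[epoch_index]
  in_epoch <- trace$time >= t0 & trace$time <= t1
  if (sum(in_epoch) < 5) stop("epoch spans fewer than 5 samples")
  if (mode == "steady") {
    idx <- trace$time >= (t1 - 0.2 * ep$duration[epoch_index]) & in_epoch
    mean(trace$current[idx])
  } else {
    dead <- 3 * trace$protocol$exchange_tau
    idx <- trace$time >= (t0 + dead) & in_epoch
    if (sum(idx) < 1) idx <- in_epoch
    y <- trace$current[idx]
    y[which.max(abs(y))]
  }
}
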