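# CSV readers/writers for the dialects the analysis consumes: long-form
# bottle volumes with per-day labels and weights, long-form region counts,
# spike timestamp lists with events, frame-wise zone traces, and
# time-current sweeps.

#' Read a two-bottle series from CSV files
#'
#' Expects a volumes CSV (`animal,timestamp,bottle,volume_ml` with bottle
#' `left`/`right`), a labels CSV (`date,left_content,right_content`), and a
#' weights CSV (`animal,date,grams`).
#'
#' @param volumes_csv,labels_csv,weights_csv File paths.
#' @param animal Animal id to extract.
#' @return A `bottle_series`.
#' @export
read_bottle_series <- function(volumes_csv, labels_csv, weights_csv,
                               animal = NULL) {
  v <- utils::read.csv(volumes_csv, stringsAsFactors = FALSE)
  if (is.null(animal)) animal <- v$animal[1]
  v <- v[v$animal == animal, , drop = FALSE]
  ts <- as.POSIXct(v$timestamp, tz = "UTC")
  wide <- stats::reshape(
    data.frame(timestamp = ts, bottle = v$bottle, volume = v$volume_ml),
    idvar = "timestamp", timevar = "bottle", direction = "wide"
  )
  names(wide) <- sub("^volume\\.", "", names(wide))
  wide <- wide[order(wide$timestamp), c("timestamp", "left", "right")]
  lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  lab$date <- as.Date(lab$date)
  w <- utils::read.csv(weights_csv, stringsAsFactors = FALSE)
  w <- w[w$animal == animal, , drop = FALSE]
  structure(
    list(animal = animal, volumes = wide, labels = lab,
         weights = data.frame(date = as.Date(w$date), grams = w$grams)),
    class = "bottle_series"
  )
}

#' Write a bottle series to the long CSV dialect
#'
#' @param series A `bottle_series`.
#' @param volumes_csv,labels_csv,weights_csv Output paths.
#' @return `volumes_csv`, invisibly.
#' @export
write_bottle_series <- function(series, volumes_csv, labels_csv,
                                weights_csv) {
  v <- series$volumes
  long <- rbind(
    data.frame(animal = series$animal, timestamp = format(v$timestamp),
               bottle = "left", volume_ml = v$left),
    data.frame(animal = series$animal, timestamp = format(v$timestamp),
               bottle = "right", volume_ml = v$right)
  )
  utils::write.csv(long, volumes_csv, row.names = FALSE)
  utils::write.csv(series$labels, labels_csv, row.names = FALSE)
  utils::write.csv(cbind(animal = series$animal, series$weights),
                   weights_csv, row.names = FALSE)
  invisible(volumes_csv)
}

#' Read region cFos counts from long-form CSV
#'
#' Expects columns `animal,group,region,count` (one row per animal-region
#' pair), the shape of ClearMap-style regional exports.
#'
#' @param path CSV path.
#' @return A `region_counts` object.
#' @export
read_region_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  regions <- unique(x$region)
  animals <- unique(x$animal)
  m <- matrix(NA_integer_, length(animals), length(regions),
              dimnames = list(animals, regions))
  m[cbind(match(x$animal, animals), match(x$region, regions))] <- x$count
  if (anyNA(m)) stop("missing animal x region cells", call. = FALSE)
  grp <- x$group[match(animals, x$animal)]
  structure(
    list(counts = m, group = factor(grp, levels = unique(grp)),
         regions = regions),
    class = "region_counts"
  )
}

#' Write region counts to long-form CSV
#'
#' @param rc A `region_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_counts <- function(rc, path) {
  long <- expand.grid(animal = rownames(rc$counts), region = rc$regions,
                      stringsAsFactors = FALSE)
  long$group <- as.character(rc$group)[match(long$animal,
                                             rownames(rc$counts))]
  long$count <- rc$counts[cbind(long$animal, long$region)]
  utils::write.csv(long[, c("animal", "group", "region", "count")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read spike trains with injection events from CSV
#'
#' Expects a spikes CSV (`unit,spike_time_s`) and an events CSV
#' (`unit,event_time_s,event_type`).
#'
#' @param spikes_csv,events_csv File paths.
#' @param duration_s Recording duration; default the last spike time.
#' @return Named list of `spike_train` objects, one per unit.
#' @export
read_spike_trains <- function(spikes_csv, events_csv, duration_s = NULL) {
  sp <- utils::read.csv(spikes_csv, stringsAsFactors = FALSE)
  ev <- utils::read.csv(events_csv, stringsAsFactors = FALSE)
  units <- unique(sp$unit)
  out <- lapply(units, function(u) {
    s <- sort(sp$spike_time_s[sp$unit == u])
    e <- ev[ev$unit == u, , drop = FALSE]
    structure(
      list(spikes = s,
           events = data.frame(time = e$event_time_s, type = e$event_type),
           duration = duration_s %||% max(s)),
      class = "spike_train"
    )
  })
  stats::setNames(out, units)
}

#' Read a frame-wise zone trace from CSV
#'
#' Expects columns `frame,zone`; the frame rate is given explicitly.
#'
#' @param path CSV path.
#' @param fps Frame rate of the trace.
#' @return A `zone_trace`.
#' @export
read_zone_trace <- function(path, fps) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  trace <- data.frame(frame = x$frame, zone = x$zone,
                      stringsAsFactors = FALSE)
  attr(trace, "fps") <- fps
  class(trace) <- c("zone_trace", "data.frame")
  trace
}

#' Read a time-current sweep from CSV
#'
#' Expects columns `time_s,current_pA` at uniform sampling.
#'
#' @param path CSV path.
#' @return A `sweep`.
#' @export
read_sweep <- function(path) {
  x <- utils::read.csv(path)
  sw <- data.frame(time_s = x$time_s, current_pA = x$current_pA)
  class(sw) <- c("sweep", "data.frame")
  attr(sw, "dt") <- stats::median(diff(x$time_s))
  sw
}
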