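# File I/O: spike tables (TSV or phy-style sorter directories), event tables,
# behaviour logs, result writers, and config files. All times are seconds as
# doubles internally; sample-index inputs are converted at load using the
# declared acquisition rate (default 30 kHz). Round-trip contract: write then
# read reproduces the object at microsecond precision.

#' Load spike data
#'
#' Reads spike-sorted unit data either from a delimited table with columns
#' `unit_id` and `spike_time_s`, or from a phy-style sorter directory
#' containing `spike_times.npy` (sample indices), `spike_clusters.npy`
#' (cluster labels) and a `params.py` declaring `sample_rate`.
#'
#' @param path File (table) or directory (phy_dir).
#' @param dialect `"table"` or `"phy_dir"`.
#' @param t_start,t_stop Optional recording bounds; default 0 and the last
#'   spike time (ceiling to the next second).
#' @param sample_rate Hz; used for `phy_dir` when `params.py` is absent.
#' @return A [spike_train_set()].
#' @export
load_spike_data <- function(path, dialect = c("table", "phy_dir"),
                            t_start = NULL, t_stop = NULL,
                            sample_rate = 30000) {
  dialect <- tryCatch(match.arg(dialect), error = function(e) {
    stop("unknown dialect; supported dialects: 'table', 'phy_dir'")
  })
  if (dialect == "table") {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("unit_id", "spike_time_s") %in% names(tab))) {
      miss <- setdiff(c("unit_id", "spike_time_s"), names(tab))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    }
    times <- as.numeric(tab$spike_time_s)
    units <- as.character(tab$unit_id)
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path)
    f_t <- file.path(path, "spike_times.npy")
    f_c <- file.path(path, "spike_clusters.npy")
    if (!file.exists(f_t) || !file.exists(f_c)) {
      stop("phy_dir requires spike_times.npy and spike_clusters.npy in ", path)
    }
    samp <- read_npy(f_t)
    clus <- read_npy(f_c)
    if (length(samp) != length(clus)) {
      stop("spike_times.npy (", length(samp), ") and spike_clusters.npy (",
           length(clus), ") have different lengths")
    }
    f_p <- file.path(path, "params.py")
    if (file.exists(f_p)) sample_rate <- read_phy_sample_rate(f_p)
    times <- samp / sample_rate
    units <- as.character(clus)
  }
  spikes <- split(times, units)
  # declared-but-silent clusters: keep zero-spike units if a cluster table exists
  if (dialect == "phy_dir") {
    f_g <- file.path(path, "cluster_group.tsv")
    if (file.exists(f_g)) {
      cg <- utils::read.delim(f_g, stringsAsFactors = FALSE)
      extra <- setdiff(as.character(cg$cluster_id), names(spikes))
      for (u in extra) spikes[[u]] <- numeric(0)
    }
  }
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_stop)) {
    t_stop <- if (length(times)) ceiling(max(times)) else t_start + 1
  }
  spike_train_set(spikes, t_start, t_stop,
                  meta = list(source = path, dialect = dialect,
                              sample_rate = sample_rate))
}

#' Write spike data as a TSV table
#'
#' @param spikes A [spike_train_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spike_data <- function(spikes, path) {
  rows <- data.frame(
    unit_id = rep(spikes$unit_ids, lengths(spikes$spikes)),
    spike_time_s = sprintf("%.6f", unlist(spikes$spikes, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an event series from a delimited table
#'
#' Required columns: `label`, `onset_s`, `duration_s`; unknown columns are
#' preserved as per-event attributes.
#'
#' @param path TSV file.
#' @return An [event_series()].
#' @export
load_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "duration_s")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(tab), need)
  attrs <- if (length(extra)) tab[, extra, drop = FALSE] else NULL
  event_series(tab$onset_s, label = tab$label[1], durations = tab$duration_s,
               attributes = attrs)
}

#' Write an event series as a TSV table
#' @param events An [event_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  tab <- data.frame(label = rep(events$label, length(events$onsets)),
                    onset_s = sprintf("%.6f", events$onsets),
                    duration_s = sprintf("%.6f", events$durations),
                    stringsAsFactors = FALSE)
  if (!is.null(events$attributes)) tab <- cbind(tab, events$attributes)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load behaviour sessions from a CSV log
#'
#' Required columns: `animal`, `day`, `trial`, `colour`, `licks`, `rewarded`.
#' One [behavior_session()] is built per (animal, day).
#'
#' @param path CSV file.
#' @return List of [behavior_session()] objects, ordered by animal then day.
#' @export
load_behavior_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "day", "trial", "colour", "licks", "rewarded")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  keys <- interaction(tab$animal, tab$day, drop = TRUE)
  parts <- split(tab, keys)
  sessions <- lapply(parts, function(p) {
    behavior_session(p$animal[1], p$day[1],
                     p[, c("trial", "colour", "licks", "rewarded")])
  })
  ord <- order(vapply(sessions, function(s) s$animal, character(1)),
               vapply(sessions, function(s) s$day, integer(1)))
  unname(sessions[ord])
}

#' Write behaviour sessions as a CSV log
#' @param sessions List of [behavior_session()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_behavior_log <- function(sessions, path) {
  rows <- do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(animal = s$animal, day = s$day,
                     stringsAsFactors = FALSE),
          s$trials[, c("trial", "colour", "licks", "rewarded")])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of analysis results to a directory
#'
#' Dispatches on object class: data.frames (burst tables, modulation tables)
#' as TSV, fitted HMMs and generic lists as JSON, spike/event containers
#' through their own writers.
#'
#' @param results Named list of result objects.
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "spike_train_set")) {
      f <- file.path(dir, paste0(nm, ".tsv")); write_spike_data(x, f)
    } else if (inherits(x, "event_series")) {
      f <- file.path(dir, paste0(nm, ".tsv")); write_events(x, f)
    } else if (inherits(x, "hmm_spec")) {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(list(transition = x$transition,
                                emission = x$emission, initial = x$initial,
                                loglik_trace = x$loglik_trace),
                           f, digits = NA, auto_unbox = TRUE)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, digits = NA, auto_unbox = TRUE)
    }
    files <- c(files, f)
  }
  invisible(files)
}

#' Read an analysis configuration file (YAML or JSON)
#' @param path Config file; format chosen by extension.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a run log capturing config, seed and package version
#' @param dir Output directory.
#' @param config Named list used for the run.
#' @param seed Integer seed used for the run.
#' @return Path of the log file, invisibly.
#' @export
write_run_log <- function(dir, config, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    list(package = "spikeburst",
         version = as.character(utils::packageVersion("spikeburst")),
         seed = seed, config = config, time = format(Sys.time())),
    f, digits = NA, auto_unbox = TRUE)
  invisible(f)
}

# ---- minimal NumPy .npy support (1-D little-endian arrays) ----------------
# phy sorter outputs are .npy; no installed R package reads the format, so a
# small reader/writer for the subset we touch lives here. Format: 6-byte
# magic, version, header length (u16 for v1, u32 for v2+), python-dict header
# with descr/fortran_order/shape, then raw data.

#' Read a 1-D NumPy `.npy` array
#'
#' Supports little-endian integer (`<i4`, `<u4`, `<i8`, `<u8`) and float
#' (`<f4`, `<f8`) 1-D arrays -- the dtypes that phy-style sorter outputs use.
#' 64-bit integers are returned as doubles (exact below 2^53).
#'
#' @param path `.npy` file.
#' @return Numeric vector.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not a .npy file: ", path)
  }
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  if (grepl("'fortran_order'\\s*:\\s*True", header)) {
    stop("fortran-order .npy arrays are not supported")
  }
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.numeric(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  n <- if (length(dims) == 0 || all(is.na(dims))) 1 else prod(dims)
  if (length(dims) > 1 && sum(dims > 1) > 1) {
    stop("only 1-D .npy arrays are supported (shape: ", shape_str, ")")
  }
  switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4,
                               endian = "little")),
    "<u4" = {
      v <- readBin(con, "integer", n, size = 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "<i8" = ,
    "<u8" = {
      r <- readBin(con, "raw", n * 8)
      lo <- readBin(r[rep(seq(0, n - 1) * 8, each = 4) +
                      rep(1:4, n)], "integer", n, size = 4,
                    endian = "little")
      hi <- readBin(r[rep(seq(0, n - 1) * 8, each = 4) +
                      rep(5:8, n)], "integer", n, size = 4,
                    endian = "little")
      lo <- ifelse(lo < 0, lo + 2^32, as.numeric(lo))
      if (descr == "<i8" && any(hi < 0)) stop("negative int64 not supported")
      hi * 2^32 + lo
    },
    stop("unsupported .npy dtype: ", descr)
  )
}

#' Write a 1-D NumPy `.npy` array
#'
#' @param x Numeric vector.
#' @param path Output file.
#' @param dtype `"<f8"` (float64), `"<i4"` (int32) or `"<i8"` (int64).
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("<f8", "<i4", "<i8")) {
  dtype <- match.arg(dtype)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }",
                    dtype, length(x))
  # pad so that magic(6)+ver(2)+hlen(2)+header is a multiple of 64, \n-terminated
  total <- 10 + nchar(header) + 1
  pad <- (64 - total %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "<f8") {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  } else if (dtype == "<i4") {
    if (any(abs(x) >= 2^31)) stop("values too large for int32")
    writeBin(as.integer(x), con, size = 4, endian = "little")
  } else {
    if (any(x < 0)) stop("negative values not supported for int64 writing")
    hi <- floor(x / 2^32)
    lo <- x - hi * 2^32
    lo <- as.integer(ifelse(lo >= 2^31, lo - 2^32, lo))
    out <- integer(2 * length(x))
    out[seq(1, by = 2, length.out = length(x))] <- lo
    out[seq(2, by = 2, length.out = length(x))] <- as.integer(hi)
    writeBin(out, con, size = 4, endian = "little")
  }
  invisible(path)
}

read_phy_sample_rate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^\\s*sample_rate\\s*=", lines, value = TRUE)
  if (!length(hit)) stop("params.py has no sample_rate entry")
  as.numeric(sub("^\\s*sample_rate\\s*=\\s*([0-9.eE+-]+).*", "\\1", hit[1]))
}
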