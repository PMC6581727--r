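#' Write a response trace as annotated CSV
#'
#' Minor-sensor traces use columns `time,input_normalized,output_normalized`
#' (plus the raw force); population traces use
#' `time_over_tauc,input_norm,detach_force_over_F0,rate_times_tauc`.
#' Normalization constants go into `# key=value` header lines. Values carry
#' 17 significant digits so the round trip is exact to machine precision.
#'
#' @param trace A `ws_response` or `ws_population`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  norm <- attr(trace, "normalization") %||% list()
  hdr <- c(
    sprintf("# trace_kind=%s", attr(trace, "trace_kind") %||% "response"),
    vapply(
      names(norm),
      function(k) sprintf("# %s=%.17g", k, norm[[k]]), character(1)
    )
  )
  if (inherits(trace, "ws_population")) {
    tau_c <- norm$tau_c %||% 1
    dat <- tibble(
      time_over_tauc = trace$time / tau_c,
      input_norm = trace$input,
      detach_force_over_F0 = trace$detach_force_norm,
      rate_times_tauc = trace$rate_norm
    )
    if ("output" %in% names(trace)) dat$output_norm <- trace$output
    dat$attached_fraction <- trace$attached
  } else {
    dat <- tibble(
      time = trace$time,
      input_normalized = trace$input,
      output_normalized = trace$output
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(dat), collapse = ","), con)
  body <- do.call(
    sprintf,
    c(
      list(paste(rep("%.17g", ncol(dat)), collapse = ",")),
      unname(as.list(dat))
    )
  )
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param path File to read.
#' @return `read_trace_csv()` returns a tibble with the file's columns and
#'   the header metadata in the `"metadata"` attribute.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    meta[[kv[1]]] <- if (is.na(val) && kv[2] != "NaN") kv[2] else val
  }
  dat <- utils::read.csv(
    text = paste(lines[!grepl("^# ", lines)], collapse = "\n")
  )
  out <- as_tibble(dat)
  attr(out, "metadata") <- meta
  out
}

#' Write run outputs and a manifest
#'
#' Writes each element of `results` according to its class — traces as
#' annotated CSV, trace summaries and other lists as JSON, ensembles as a
#' JSON-lines event list plus a binned CSV — then a `manifest.json` listing
#' every file with its MD5 checksum, the package version, and any extra
#' metadata (scenario name, seed).
#'
#' @param results A named list of result objects.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @param manifest_extra Named list merged into the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, formats = c("csv", "json"),
                          manifest_extra = list()) {
  stopifnot(is.list(results))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort(sprintf("Cannot create output directory '%s'.", out_dir),
        class = "wallsense_unwritable"
      )
    }
  }
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "ws_response") || inherits(x, "ws_population")) {
      if ("csv" %in% formats) {
        p <- file.path(out_dir, paste0(nm, ".csv"))
        write_trace_csv(x, p)
        files <- c(files, p)
      }
    } else if (inherits(x, "ws_ensemble")) {
      if ("json" %in% formats) {
        p <- file.path(out_dir, paste0(nm, "_events.jsonl"))
        con <- file(p, "w")
        writeLines(
          sprintf(
            '{"time":%.17g,"force":%.17g,"sensor_id":%d}',
            x$events$time, x$events$force, x$events$sensor
          ),
          con
        )
        close(con)
        files <- c(files, p)
      }
      if ("csv" %in% formats) {
        p <- file.path(out_dir, paste0(nm, "_binned.csv"))
        utils::write.csv(x$binned, p, row.names = FALSE)
        files <- c(files, p)
      }
    } else if (inherits(x, "ws_signal")) {
      if ("csv" %in% formats) {
        p <- file.path(out_dir, paste0(nm, ".csv"))
        write_signal_csv(x, p)
        files <- c(files, p)
      }
    } else if ("json" %in% formats) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      obj <- if (is.data.frame(x)) as.list(as_tibble(x)) else x
      jsonlite::write_json(obj, p,
        auto_unbox = TRUE, digits = NA,
        force = TRUE, pretty = TRUE
      )
      files <- c(files, p)
    }
  }
  manifest <- c(
    list(
      package = "wallsense",
      version = as.character(utils::packageVersion("wallsense")),
      created = format(Sys.time(), tz = "UTC"),
      files = lapply(files, function(f) {
        list(name = basename(f), md5 = unname(tools::md5sum(f)))
      })
    ),
    manifest_extra
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(manifest)
}
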