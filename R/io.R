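# Configuration loading with unit-bearing key names, and self-describing
# CSV export/import for the three measurement products.

.known_config_keys <- function() list(
  stack     = names(formals(sensor_stack)),
  chemistry = names(formals(surface_chemistry)),
  enzyme    = names(formals(enzyme_layer)),
  circuit   = names(formals(circuit_params)),
  solution  = c("ph", "penicillin_mm")
)

.build_section <- function(cfg, section, constructor, path) {
  given <- cfg[[section]]
  if (is.null(given)) given <- list()
  if (!is.list(given))
    stop(sprintf("config section '%s' must be a mapping (%s)", section, path),
         call. = FALSE)
  known <- .known_config_keys()[[section]]
  unknown <- setdiff(names(given), known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in config section '%s': %s (known: %s)",
                 section, paste(unknown, collapse = ", "),
                 paste(known, collapse = ", ")),
         call. = FALSE)
  do.call(constructor, given)
}

#' Load and validate a device configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file with sections
#' `stack`, `chemistry`, `enzyme`, `circuit`, `solution` and an optional
#' top-level `rng_seed`. Key names carry their units (`d_sio2_nm`,
#' `area_mm2`, `r_series_ohm`, ...) and map 1:1 to the constructor arguments
#' of [sensor_stack()], [surface_chemistry()], [enzyme_layer()],
#' [circuit_params()] and [solution_state()]. Omitted fields take the
#' documented defaults; unknown keys and invariant violations raise
#' descriptive errors. On success the insulator capacitance implied by the
#' stack is echoed as a load-time self-check.
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the self-check message.
#' @return An [eiscap_device()] built from the configuration.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml or .json)",
         call. = FALSE))
  if (!is.list(cfg)) stop("config root must be a mapping: ", path, call. = FALSE)
  unknown <- setdiff(names(cfg),
                     c(names(.known_config_keys()), "rng_seed"))
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dev <- eiscap_device(
    stack    = .build_section(cfg, "stack", sensor_stack, path),
    chem     = .build_section(cfg, "chemistry", surface_chemistry, path),
    enzyme   = .build_section(cfg, "enzyme", enzyme_layer, path),
    circuit  = .build_section(cfg, "circuit", circuit_params, path),
    solution = .build_section(cfg, "solution", solution_state, path),
    rng_seed = cfg$rng_seed %||% 1L)
  if (!quiet)
    message(sprintf("loaded device config '%s': insulator capacitance %.2f nF",
                    basename(path), insulator_capacitance(dev$stack) * 1e9))
  dev
}

#' Read a solution schedule file
#'
#' CSV with columns `label`, `ph`, `penicillin_mm`, `duration_s` (one row per
#' segment, in order).
#'
#' @param path Path to the schedule CSV.
#' @return A [solution_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "ph", "penicillin_mm", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  solution_schedule(df$label, df$ph, df$penicillin_mm, df$duration_s)
}

# md5 of the canonical JSON rendering of the device description
.config_hash <- function(device) {
  js <- jsonlite::toJSON(list(
    stack = unclass(device$stack), chemistry = unclass(device$chem),
    enzyme = unclass(device$enzyme), circuit = unclass(device$circuit),
    solution = unclass(device$solution)), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

.product_columns <- list(
  impedance_spectrum = c("frequency_hz", "zmag_ohm", "phase_deg"),
  cv_curve = c("voltage_v", "capacitance_f"),
  concap_trace = c("time_s", "voltage_v", "capacitance_f", "segment")
)

.header_meta <- function(x) {
  type <- intersect(class(x), names(.product_columns))[1]
  meta <- switch(type,
    impedance_spectrum = list(v_gate = attr(x, "v_gate")),
    cv_curve = {
      sol <- attr(x, "solution")
      c(list(freq_hz = attr(x, "freq_hz"),
             ac_amplitude_v = attr(x, "ac_amplitude_v")),
        if (!is.null(sol)) list(solution_ph = sol$ph,
                                solution_penicillin_mm = sol$penicillin_mm))
    },
    concap_trace = {
      g <- attr(x, "gains")
      list(c_wp_f = attr(x, "c_wp"), dt_s = g$dt, kp = g$kp, ki = g$ki,
           kd = g$kd, tolerance_f = g$tolerance)
    })
  meta
}

#' Write a measurement product to CSV
#'
#' Writes an [run_impedance_spectrum()] spectrum, [run_cv_sweep()] curve or
#' [run_concap()] trace as CSV with `#`-prefixed metadata header lines
#' (product type, mode settings, optional device-configuration hash and
#' seed). Numeric columns are written with 15 significant digits so a
#' write/read round trip is lossless to at least 12 significant digits.
#'
#' @param x The product object.
#' @param path Output file path.
#' @param device Optional device the product was measured on; its
#'   configuration hash and seed are recorded in the header.
#' @param ... Ignored.
#' @return `path`, invisibly.
#' @export
write_product <- function(x, path, device = NULL, ...) {
  type <- intersect(class(x), names(.product_columns))[1]
  if (is.na(type))
    stop("not a writable product (expected impedance_spectrum, cv_curve ",
         "or concap_trace)", call. = FALSE)
  if (nrow(x) == 0) stop("refusing to write an empty product", call. = FALSE)
  meta <- .header_meta(x)
  if (!is.null(device)) {
    meta$config_md5 <- .config_hash(device)
    meta$rng_seed <- device$rng_seed
  }
  hdr <- c(sprintf("# eiscap product=%s", type),
           vapply(names(meta), function(k)
             sprintf("# %s=%s", k, format(meta[[k]], digits = 15)),
             character(1)))
  df <- as.data.frame(x)
  for (cn in names(df))
    if (is.numeric(df[[cn]])) df[[cn]] <- formatC(df[[cn]], digits = 15,
                                                  format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement product written by [write_product()]
#'
#' @param path Path to the CSV file.
#' @return The reconstructed product object (`impedance_spectrum`,
#'   `cv_curve` or `concap_trace`); header metadata is restored as
#'   attributes (`meta` holds the full key-value list).
#' @export
read_product <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (!length(hdr_idx) || !grepl("^# eiscap product=", lines[1]))
    stop("parse error at line 1: missing '# eiscap product=' header in ",
         path, call. = FALSE)
  type <- sub("^# eiscap product=", "", lines[1])
  if (!type %in% names(.product_columns))
    stop("parse error at line 1: unknown product type '", type, "'",
         call. = FALSE)
  meta <- list()
  for (i in setdiff(hdr_idx, 1L)) {
    kv <- sub("^# ", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop("parse error at line ", i, ": malformed header '",
                     lines[i], "'", call. = FALSE)
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  miss <- setdiff(.product_columns[[type]], names(df))
  if (length(miss))
    stop("parse error at line ", max(hdr_idx) + 1L, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("empty product in ", path, call. = FALSE)
  out <- switch(type,
    impedance_spectrum = structure(df,
      class = c("impedance_spectrum", "data.frame"), v_gate = meta$v_gate),
    cv_curve = cv_curve(df$voltage_v, df$capacitance_f,
                        freq_hz = meta$freq_hz %||% 120,
                        ac_amplitude_v = meta$ac_amplitude_v %||% 0.02,
                        solution = if (!is.null(meta$solution_ph))
                          solution_state(meta$solution_ph,
                                         meta$solution_penicillin_mm %||% 0)),
    concap_trace = structure(df,
      class = c("concap_trace", "data.frame"), c_wp = meta$c_wp_f,
      warnings = character(0)))
  attr(out, "meta") <- meta
  out
}
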