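#' Table schema for delimited text I/O
#'
#' Column names carry their units (e.g. `shear_rate_1_s`, `width_mm`) so a
#' table is unambiguous on its own; a leading `#` comment block documents
#' them in prose.
#'
#' @param columns Character vector of required column names.
#' @param units Optional character vector (same length) of unit strings for
#'   the header comment.
#' @param delimiter Field delimiter, default comma (tab accepted on read).
#' @return A `table_schema` list.
#' @export
table_schema <- function(columns, units = NULL, delimiter = ",") {
  if (!is.null(units) && length(units) != length(columns))
    stop("units must match columns")
  structure(list(columns = columns, units = units, delimiter = delimiter),
            class = "table_schema")
}

#' Write a data frame as a delimited text table
#'
#' Writes a `#`-prefixed comment header documenting the units, then a
#' header row and the data.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param schema Optional [table_schema()]; defaults to the data frame's
#'   columns with no unit comments.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = NULL) {
  if (is.null(schema)) schema <- table_schema(names(df))
  missing <- setdiff(schema$columns, names(df))
  if (length(missing)) stop(sprintf("data frame lacks column(s): %s", paste(missing, collapse = ", ")))
  df <- df[schema$columns]
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(schema$units))
    writeLines(sprintf("# %s: %s", schema$columns, schema$units), con)
  writeLines(paste(schema$columns, collapse = schema$delimiter), con)
  apply_fmt <- function(row) paste(vapply(row, format, character(1L), digits = 12),
                                   collapse = schema$delimiter)
  writeLines(vapply(seq_len(nrow(df)), function(i) apply_fmt(df[i, , drop = TRUE]),
                    character(1L)), con)
  invisible(path)
}

#' Read a delimited text table against a schema
#'
#' Skips blank lines and `#` comments, matches the header row against the
#' schema order-insensitively, and parses every field as a number, naming
#' the offending line on failure.
#'
#' @param path File to read.
#' @param schema A [table_schema()] naming the required columns.
#' @return A data frame with the schema's columns in schema order (extra
#'   file columns are kept after them).
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no content rows in file")
  delim <- if (grepl("\t", raw[keep[1L]])) "\t" else schema$delimiter
  split1 <- function(s) trimws(strsplit(s, delim, fixed = TRUE)[[1L]])
  header <- split1(raw[keep[1L]])
  missing <- setdiff(schema$columns, header)
  if (length(missing))
    stop(sprintf("missing column(s) in %s: %s", path, paste(missing, collapse = ", ")))
  rows <- keep[-1L]
  vals <- matrix(NA_real_, length(rows), length(header))
  for (ii in seq_along(rows)) {
    fields <- split1(raw[rows[ii]])
    if (length(fields) != length(header))
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   rows[ii], path, length(header), length(fields)))
    x <- suppressWarnings(as.numeric(fields))
    if (any(is.na(x)))
      stop(sprintf("line %d of %s: unparsable number '%s' in column '%s'",
                   rows[ii], path, fields[which(is.na(x))[1L]],
                   header[which(is.na(x))[1L]]))
    vals[ii, ] <- x
  }
  df <- as.data.frame(vals)
  names(df) <- header
  df[, c(schema$columns, setdiff(header, schema$columns)), drop = FALSE]
}

# schemas for the package's standard data products
.schema_rheogram <- function() table_schema(
  c("shear_rate_1_s", "viscosity_Pa_s"), c("1/s", "Pa.s"))
.schema_ramp <- function() table_schema(
  c("temperature_C", "viscosity_Pa_s"), c("degC", "Pa.s"))
.schema_oscillatory <- function() table_schema(
  c("temperature_C", "G_storage_Pa", "G_loss_Pa"), c("degC", "Pa", "Pa"))
.schema_widths <- function() table_schema(
  c("inlet_velocity_mm_s", "width_mm"), c("mm/s", "mm"))

#' Read a simulation run configuration
#'
#' YAML file with optional sections `geometry`, `material`, `conditions`,
#' `grid`, `thermostat`, `convection`, `deposition`; every key is optional
#' and defaults to the package's constructor defaults (which are the
#' studied device's printed values where printed). The fully resolved
#' configuration is returned and can be echoed to a run log so a run is
#' reproducible from its log alone.
#'
#' @param path YAML file path.
#' @param rheology A [power_law_model()] for the material (the config's
#'   `material` section may override `k`, `n`, `b`, `T_ref`).
#' @return List with resolved `geometry`, `conditions`, `material`, `grid`,
#'   `thermostat`, `convection`, `deposition`.
#' @export
read_run_config <- function(path, rheology = power_law_model(k = 5, n = 0.5, b = 0.03)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  build <- function(ctor, args) do.call(ctor, args[names(args) %in% names(formals(ctor))])
  mat_args <- cfg$material %||% list()
  # YAML 1.1 reads a bare `n` key as boolean FALSE; rescue it (and accept the
  # unambiguous alias `n_index`)
  names(mat_args)[names(mat_args) == "FALSE"] <- "n"
  names(mat_args)[names(mat_args) == "n_index"] <- "n"
  rheo_over <- mat_args[names(mat_args) %in% c("k", "n", "b", "T_ref")]
  if (length(rheo_over)) {
    base <- list(k = rheology$k, n = rheology$n, T_ref = rheology$T_ref, b = rheology$b)
    base[names(rheo_over)] <- rheo_over
    rheology <- do.call(power_law_model, base)
  }
  mat_args <- mat_args[!names(mat_args) %in% c("k", "n", "b", "T_ref")]
  conditions_args <- cfg$conditions %||% list()
  if (is.null(conditions_args$inlet_velocity)) conditions_args$inlet_velocity <- 0.03
  conv_args <- cfg$convection %||% list()
  if (!is.null(conv_args$characteristic_length_m)) {
    conv_args$L <- conv_args$characteristic_length_m
    conv_args$characteristic_length_m <- NULL
  }
  list(
    geometry = build(channel_geometry, cfg$geometry %||% list()),
    conditions = build(process_conditions, conditions_args),
    material = build(material_properties, c(list(rheology = rheology), mat_args)),
    grid = build(grid_spec, cfg$grid %||% list()),
    thermostat = build(thermostat_state, cfg$thermostat %||% list()),
    convection = build(convection_config, conv_args),
    deposition = cfg$deposition %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append a timestamped, level-tagged line to a run log
#'
#' @param msg Message (sprintf-style with `...`).
#' @param ... Values interpolated into `msg`.
#' @param level Tag, default `"INFO"`.
#' @param file Log file path, or `""` for console.
#' @return The formatted line, invisibly.
#' @export
log_line <- function(msg, ..., level = "INFO", file = "") {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(msg, ...))
  cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}
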