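## ------------------------------------------------------------------
## Configuration parsing, metadata-carrying tabular output, and
## deterministic fixture generation.
## ------------------------------------------------------------------

config_keys <- c("u", "h", "schedule", "N", "x0", "t_max", "seed", "out",
                 "format", "dense_max", "cap")

#' Parse a run configuration (YAML/JSON)
#'
#' Reads a flat-key configuration document describing a model run. Accepted
#' keys: `u`, `h` *or* `schedule` (list of `{t_start, h}` epochs), `N`
#' (number or `"inf"`), `x0` (number, `"equilibrium"` or `"stationary"`),
#' `t_max`, `seed`, `out`, `format`, `dense_max`, `cap`. Unknown keys are
#' rejected with a listing; parameter bounds are validated with
#' field-level messages.
#'
#' @param text A YAML (or JSON, a YAML subset) document as a single string,
#'   or a file path to one.
#' @return A validated list of class `"run_config"`.
#' @examples
#' cfg <- parse_config("u: 1.0e-8\nh: 0\nN: inf\nt_max: 100")
#' cfg$N
#' @export
parse_config <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  doc <- if (file.exists(text) && !grepl("\n", text))
    yaml::read_yaml(text) else yaml::yaml.load(text)
  if (!is.list(doc)) stop("config must be a mapping of keys to values",
                          call. = FALSE)
  ## YAML 1.1 treats a bare key `N` as a boolean literal; map it back
  names(doc)[names(doc) == "FALSE"] <- "N"
  ## YAML 1.1 floats require a decimal point, so "1e-8" arrives as a string;
  ## coerce numeric-looking strings in numeric fields
  as_num <- function(v) {
    if (is.character(v) && length(v) == 1L &&
        !is.na(suppressWarnings(w <- as.numeric(v)))) w else v
  }
  for (f in c("u", "h", "t_max", "seed", "dense_max", "cap"))
    if (!is.null(doc[[f]])) doc[[f]] <- as_num(doc[[f]])
  if (!is.null(doc$x0) && !identical(doc$x0, "equilibrium") &&
      !identical(doc$x0, "stationary")) doc$x0 <- as_num(doc$x0)
  if (!is.null(doc$N) && !identical(doc$N, "inf") &&
      !identical(doc$N, "Inf")) doc$N <- as_num(doc$N)
  unknown <- setdiff(names(doc), config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; accepted keys are: ", paste(config_keys, collapse = ", "),
         call. = FALSE)
  if (is.null(doc$u)) stop("config field 'u' is required", call. = FALSE)
  if (!is.numeric(doc$u) || doc$u < 0 || doc$u > 1)
    stop("config field 'u' must be a probability in [0, 1]", call. = FALSE)
  if (!is.null(doc$h) && !is.null(doc$schedule))
    stop("give either 'h' or 'schedule', not both", call. = FALSE)
  if (!is.null(doc$h) && (!is.numeric(doc$h) || doc$h > 1))
    stop("config field 'h' must be numeric with h <= 1 ",
         "(heterozygote fitness cannot be negative)", call. = FALSE)
  if (!is.null(doc$schedule)) {
    ts <- vapply(doc$schedule, function(e) as.numeric(e$t_start), numeric(1))
    hh <- vapply(doc$schedule, function(e) as.numeric(e$h), numeric(1))
    doc$schedule <- dominance_schedule(ts, hh)  # validates
  }
  if (!is.null(doc$N)) {
    if (identical(doc$N, "inf") || identical(doc$N, "Inf")) doc$N <- Inf
    else if (!is.numeric(doc$N) || doc$N < 1 || doc$N != round(doc$N))
      stop("config field 'N' must be a positive integer or \"inf\"",
           call. = FALSE)
  }
  if (!is.null(doc$x0) && is.numeric(doc$x0)) assert_frequency(doc$x0, "x0")
  if (!is.null(doc$t_max) &&
      (!is.numeric(doc$t_max) || doc$t_max < 0 ||
       doc$t_max != round(doc$t_max)))
    stop("config field 't_max' must be a non-negative integer", call. = FALSE)
  structure(doc, class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' Inverse of [parse_config()]: `parse_config(format_config(cfg))` returns
#' an equivalent configuration.
#'
#' @param config A `"run_config"` list.
#' @return A single YAML string.
#' @export
format_config <- function(config) {
  x <- unclass(config)
  if (!is.null(x$schedule) && inherits(x$schedule, "dominance_schedule")) {
    x$schedule <- lapply(seq_along(x$schedule$t_start), function(i)
      list(t_start = x$schedule$t_start[i],
           h = sprintf("%.17g", x$schedule$h[i])))
  }
  if (!is.null(x$N) && is.infinite(x$N)) x$N <- "inf"
  ## doubles are serialized as %.17g strings so values survive the round
  ## trip bit-exactly (the YAML emitter trims significant digits)
  for (f in names(x))
    if (is.double(x[[f]]) && length(x[[f]]) == 1L && is.finite(x[[f]]) &&
        x[[f]] != round(x[[f]]))
      x[[f]] <- sprintf("%.17g", x[[f]])
  yaml::as.yaml(x)
}

#' Write a table with a metadata header
#'
#' Writes a data frame as TSV (default) or CSV with `#`-prefixed metadata
#' lines (tool version, configuration, seed, ...) followed by a header row.
#' Floating-point columns are written with enough digits to round-trip
#' bit-exactly; newlines are POSIX `\n`.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param meta Named list of metadata values written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv"), meta = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, open = "wb")  # binary: POSIX newlines on any platform
  on.exit(close(con))
  header <- c(sprintf("# lethalWF %s",
                      as.character(utils::packageVersion("lethalWF"))),
              vapply(names(meta), function(k)
                sprintf("# %s: %s", k, format(meta[[k]], digits = 17)),
                character(1)))
  fmt_col <- function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }
  body <- if (nrow(rows))
    do.call(paste, c(lapply(rows, fmt_col), sep = sep)) else character(0)
  writeLines(c(header, paste(names(rows), collapse = sep), body), con,
             sep = "\n")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @return A data frame; `#` metadata lines are returned in attribute
#'   `"meta"` (as raw strings).
#' @export
read_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  sep <- if (format == "tsv") "\t" else ","
  out <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Deterministic bundle of small reference inputs
#'
#' Builds, in code, the small reference objects used for validation:
#' tiny chains (`N` in 1..3) with brute-force stationary vectors obtained
#' by eigen-decomposition, the closed-form recessive-lethal trajectory
#' `x_t = x0 / (1 + t x0)` (for `h = 0`, `u = 0`), and the parameter grids
#' used for stationary-frequency and half-time tables.
#'
#' @param seed Integer seed (the bundle is fully deterministic; the seed is
#'   recorded and used for any randomised entries).
#' @return Named list with elements `chains`, `closed_form`,
#'   `table1_grid`, `table2_grid`, `seed`.
#' @export
make_fixtures <- function(seed = 1L) {
  set.seed(seed)
  chains <- lapply(1:3, function(N) {
    m <- lethal_model(u = 0.1, h = 0, N = N)
    W <- transition_matrix(m)
    ## brute-force stationary vector: eigenvector of eigenvalue 1
    e <- eigen(W)
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    list(model = m, W = W, pi_bruteforce = v)
  })
  x0 <- 0.5
  tt <- 0:50
  closed_form <- data.frame(t = tt, x = x0 / (1 + tt * x0))
  table1_grid <- expand.grid(h = c(-0.01, -0.001, 0, 0.001, 0.01),
                             N = c(500, 1000, 2000, Inf),
                             u = c(1e-8, 1e-5), KEEP.OUT.ATTRS = FALSE)
  table1_grid <- table1_grid[, c("u", "N", "h")]
  table2_grid <- expand.grid(N = c(500, 1000, 2000, Inf),
                             jump = c("0->-0.01", "-0.01->0"),
                             u = c(1e-8, 1e-5), KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  table2_grid <- table2_grid[, c("u", "N", "jump")]
  list(chains = chains, closed_form = closed_form,
       table1_grid = table1_grid, table2_grid = table2_grid,
       seed = seed)
}
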