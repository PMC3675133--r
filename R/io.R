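#' Write / read binary pattern files
#'
#' Vocabularies and training sets are stored as plain text, one pattern per
#' line as contiguous binary digits, for inspection and reproducibility.
#'
#' @param x A [generate_vocabulary()] object, a [make_training_set()]
#'   tibble, or a 0/1 matrix (patterns in rows).
#' @param path Output file path.
#' @return `write_patterns()` returns `path` invisibly; `read_patterns()`
#'   returns a 0/1 integer matrix with one pattern per row.
#' @export
write_patterns <- function(x, path) {
  m <- if (inherits(x, "slot_vocabulary")) {
    x$entries
  } else if (is.data.frame(x) && "ec_vector" %in% names(x)) {
    do.call(rbind, x$ec_vector)
  } else {
    x
  }
  writeLines(apply(m, 1, paste, collapse = ""), path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  m <- suppressWarnings(do.call(rbind, lapply(strsplit(lines, ""), as.integer)))
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    stop("pattern file ", path, " contains non-binary characters")
  }
  m
}

#' Checkpoint network weights to a plain-text file
#'
#' All projection weight matrices are written to one text file: a header
#' line `>name nrow ncol` per projection followed by one whitespace-
#' separated row of weights per sender.
#'
#' @param network A `hippo_network`.
#' @param path Output file path.
#' @return `write_weights()` returns `path` invisibly.
#' @export
write_weights <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(network$projections)) {
    w <- network$projections[[nm]]$W
    writeLines(sprintf(">%s %d %d", nm, nrow(w), ncol(w)), con)
    utils::write.table(w, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(network, path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  weights <- list()
  for (h in seq_along(headers)) {
    parts <- strsplit(sub("^>", "", lines[headers[h]]), " ")[[1]]
    nm <- parts[1]
    nr <- as.integer(parts[2])
    block <- lines[(headers[h] + 1):(headers[h] + nr)]
    weights[[nm]] <- do.call(rbind, lapply(strsplit(block, " +"), as.numeric))
  }
  set_network_weights(network, weights)
}

#' Write / read a capacity result table
#'
#' Results are stored as tab-separated text preceded by a `#`-prefixed
#' metadata block recording every experiment parameter. Per-pattern error
#' vectors are serialised as comma strings so the file round-trips the full
#' result, including what [bootstrap_compare()] needs.
#'
#' @param result A [capacity_sweep()] tibble.
#' @param path File path.
#' @param exp_config Optional [experiment_config()] written into the
#'   metadata block (taken from the result's attribute when absent).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a `capacity_result` tibble.
#' @export
write_results <- function(result, path, exp_config = NULL) {
  if (is.null(exp_config)) exp_config <- attr(result, "exp_config")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(package_version = as.character(utils::packageVersion("thetahippo")))
  if (!is.null(exp_config)) {
    meta <- c(meta,
              conditions = paste(exp_config$conditions, collapse = ","),
              ca3_sizes = paste(exp_config$ca3_sizes, collapse = ","),
              set_sizes = paste(exp_config$set_sizes, collapse = ","),
              n_seeds = exp_config$n_seeds, n_epochs = exp_config$n_epochs,
              base_seed = exp_config$base_seed,
              eps = exp_config$config$eps,
              n_slots = exp_config$config$n_slots,
              slot_size = exp_config$config$slot_size,
              n_active = exp_config$config$n_active)
  }
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  tab <- result
  tab$errors <- vapply(result$errors, paste, character(1), collapse = ",")
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$errors <- lapply(strsplit(as.character(tab$errors), ","), as.integer)
  out <- tibble::as_tibble(tab)
  class(out) <- c("capacity_result", class(out))
  out
}

#' Log a theta-cycle trace to a tabular file
#'
#' Writes one row per (phase, layer, unit) with the unit's end-of-phase
#' activation — the optional per-trial instrumentation used to inspect
#' settling.
#'
#' @param trace A [run_theta_cycle()] trace.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "theta_trace"))
  rows <- do.call(rbind, lapply(names(trace$phases), function(ph) {
    do.call(rbind, lapply(names(trace$phases[[ph]]), function(l) {
      y <- trace$phases[[ph]][[l]]
      data.frame(phase = ph, layer = l, unit = seq_along(y), y = y)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
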