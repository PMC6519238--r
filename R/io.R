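# Delimited-text input/output. Tables are plain TSV/CSV so results slot
# into shell pipelines; no binary formats.

#' Read a survival table from delimited text
#'
#' Expects a header row with a time column, a status column, and one column
#' per covariate (rows = samples). The delimiter is auto-detected by
#' \code{data.table::fread}.
#'
#' @param path file path (.csv/.tsv/.txt).
#' @param time_col,status_col names of the time and status columns
#'   (defaults "time", "status").
#' @param transpose if TRUE the covariate part of the table is transposed
#'   before assembly (for matrices shipped genes-in-rows this is NOT the
#'   right tool; transpose applies to a samples-in-columns covariate block
#'   read alongside per-sample time/status columns and is rarely needed --
#'   see the CLI \code{--transpose} flag for whole-matrix pivoting).
#' @return a \code{\link{survival_sample}}.
#' @export
read_survival_table <- function(path, time_col = "time", status_col = "status",
                                transpose = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (transpose) {
    dt <- transpose_matrix_table(dt, time_col, status_col)
  }
  if (!(time_col %in% names(dt))) stop("missing required column '", time_col, "'")
  if (!(status_col %in% names(dt))) stop("missing required column '", status_col, "'")
  cov_cols <- setdiff(names(dt), c(time_col, status_col))
  if (length(cov_cols) == 0) stop("no covariate columns found")

  non_num <- cov_cols[!vapply(dt[cov_cols], is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric covariate column(s): ", paste(non_num, collapse = ", "))

  complete <- stats::complete.cases(dt)
  if (!all(complete)) {
    stop(sum(!complete), " row(s) contain missing values; ",
         "impute or drop them before scoring (first offending row: ",
         which(!complete)[1], ")")
  }
  tm <- dt[[time_col]]
  st <- dt[[status_col]]
  if (any(tm <= 0)) stop("nonpositive time in row ", which(tm <= 0)[1],
                         " (log time undefined)")
  if (!all(st %in% c(0, 1))) stop("non-binary status in row ",
                                  which(!(st %in% c(0, 1)))[1])
  survival_sample(tm, st, as.matrix(dt[cov_cols]))
}

# pivot a genes-in-rows matrix (first column = feature names, remaining
# columns = samples) into samples-in-rows; time/status must already be rows
# of the matrix
transpose_matrix_table <- function(dt, time_col, status_col) {
  feat <- as.character(dt[[1]])
  M <- t(as.matrix(dt[, -1, drop = FALSE]))
  out <- as.data.frame(M, stringsAsFactors = FALSE)
  names(out) <- feat
  for (j in seq_along(out)) out[[j]] <- as.numeric(out[[j]])
  out
}

#' Write a ranked score table
#'
#' Writes one row per covariate with columns \code{covariate}, \code{score},
#' \code{abs_rank}, \code{marginal_corr} (CARS only) and, when a selection
#' is supplied, \code{q_value} and \code{selected}. Output is deterministic
#' and round-trips through \code{data.table::fread} at full precision.
#'
#' @param result a \code{cars_result} or \code{cox_score_vector}.
#' @param path output path (delimiter chosen by extension: .csv else tab).
#' @param selection optional result of \code{\link{select_markers}} computed
#'   on the same scores.
#' @return invisibly, the data.frame written.
#' @export
write_score_table <- function(result, path, selection = NULL) {
  if (inherits(result, "cars_result")) {
    df <- data.frame(covariate = names(result$scores),
                     score = unname(result$scores),
                     abs_rank = result$abs_rank,
                     marginal_corr = unname(result$marginal_corr),
                     stringsAsFactors = FALSE)
  } else if (inherits(result, "cox_score_vector")) {
    z <- result$z_scores
    df <- data.frame(covariate = names(z), score = unname(z),
                     abs_rank = rank_by_magnitude(z),
                     stringsAsFactors = FALSE)
  } else stop("result must be a cars_result or cox_score_vector")

  if (!is.null(selection)) {
    df$q_value <- selection$fit$q_values
    df$selected <- selection$selected
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data.table::fwrite(df, path, sep = sep)
  invisible(df)
}

#' Read a scenario-grid configuration
#'
#' YAML file with scalar or list-valued scenario fields (\code{n}, \code{d},
#' \code{rel_var}, \code{exp_var}, \code{cens_rate}, \code{signal_block},
#' \code{family}, \code{snr}; lists are crossed) plus optional
#' \code{replications}, \code{base_seed} and \code{pilot_size}.
#'
#' @param path YAML file path.
#' @return list with \code{scenarios} (data.frame), \code{replications},
#'   \code{base_seed}, \code{pilot_size}.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep YAML-1.1 boolean-like keys ("n", "y") as literal strings: the
  # scenario field n would otherwise be read as the key FALSE
  keep <- function(x) x
  cfg <- yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                         handlers = list("bool#no" = keep, "bool#yes" = keep))
  grid_args <- cfg[intersect(names(cfg),
                             c("n", "d", "rel_var", "exp_var", "cens_rate",
                               "signal_block", "family", "snr"))]
  scenarios <- do.call(scenario_grid, grid_args)
  list(scenarios = scenarios,
       replications = cfg$replications %||% 10L,
       base_seed = cfg$base_seed %||% 1L,
       pilot_size = cfg$pilot_size %||% 1e5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
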