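# Canonical trial-log schema (human-facing files use 1-based rows/cols).
trial_log_columns <- function() {
  c("participant_id", "condition", "pair_id", "session", "trial",
    "choice_row", "choice_col", "reward", "partner_prev_row",
    "partner_prev_col")
}

#' Write a cohort to a trial-log file
#'
#' Comma-separated UTF-8 text, one row per trial, with 1-based `(row, col)`
#' coordinates; partner columns are empty for solo participants and on
#' trial 1.
#'
#' @param cohort List of [participant_data()] (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  if (inherits(cohort, "participant_data")) cohort <- list(cohort)
  rows <- lapply(cohort, function(pd) {
    xy <- option_coordinates(pd$grid, pd$records$choice)
    pp <- pd$records$partner_prev_choice
    has_pp <- !is.na(pp)
    prow <- pcol <- rep(NA_integer_, length(pp))
    if (any(has_pp)) {
      pxy <- option_coordinates(pd$grid, pp[has_pp])
      prow[has_pp] <- pxy[, "row"] + 1L
      pcol[has_pp] <- pxy[, "col"] + 1L
    }
    data.frame(participant_id = pd$participant_id, condition = pd$condition,
               pair_id = ifelse(is.na(pd$pair_id), "", as.character(pd$pair_id)),
               session = pd$records$session, trial = pd$records$trial,
               choice_row = xy[, "row"] + 1L, choice_col = xy[, "col"] + 1L,
               reward = pd$records$reward,
               partner_prev_row = prow, partner_prev_col = pcol)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

# Validate and convert a canonical-schema data.frame into participant_data.
parse_trials <- function(df, grid = grid_spec(), source = "<data>") {
  missing_cols <- setdiff(trial_log_columns(), names(df))
  if (length(missing_cols)) {
    stop(source, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(source, ": ", what, " (lines ",
           paste(utils::head(line_no[which(cond)], 5), collapse = ", "), ")")
    }
  }
  for (cl in c("session", "trial", "choice_row", "choice_col")) {
    v <- df[[cl]]
    bad_row(is.na(suppressWarnings(as.numeric(v))) |
              suppressWarnings(as.numeric(v)) %% 1 != 0,
            paste0("non-integer values in '", cl, "'"))
    df[[cl]] <- as.integer(df[[cl]])
  }
  bad_row(!is.finite(suppressWarnings(as.numeric(df$reward))),
          "non-numeric values in 'reward'")
  df$reward <- as.numeric(df$reward)
  bad_row(df$choice_row < 1L | df$choice_row > grid$n_rows,
          paste0("'choice_row' outside 1..", grid$n_rows))
  bad_row(df$choice_col < 1L | df$choice_col > grid$n_cols,
          paste0("'choice_col' outside 1..", grid$n_cols))
  bad_row(!df$condition %in% c("solo", "pair"),
          "'condition' must be 'solo' or 'pair'")
  for (cl in c("partner_prev_row", "partner_prev_col")) {
    v <- df[[cl]]
    v[v %in% c("", "NA")] <- NA
    df[[cl]] <- suppressWarnings(as.integer(v))
  }
  has_pp <- !is.na(df$partner_prev_row) | !is.na(df$partner_prev_col)
  bad_row(df$condition == "solo" & has_pp,
          "solo-condition rows must not carry partner columns")
  bad_row(has_pp & (is.na(df$partner_prev_row) | is.na(df$partner_prev_col)),
          "partner columns must be both present or both empty")
  bad_row(has_pp & (df$partner_prev_row < 1L | df$partner_prev_row > grid$n_rows |
                      df$partner_prev_col < 1L | df$partner_prev_col > grid$n_cols),
          "partner coordinates outside the grid")

  lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$session, g$trial), , drop = FALSE]
    pp <- rep(NA_integer_, nrow(g))
    hp <- !is.na(g$partner_prev_row)
    if (any(hp)) {
      pp[hp] <- option_index(grid, g$partner_prev_row[hp] - 1L,
                             g$partner_prev_col[hp] - 1L)
    }
    records <- data.frame(
      session = g$session, trial = g$trial,
      choice = option_index(grid, g$choice_row - 1L, g$choice_col - 1L),
      reward = g$reward, partner_prev_choice = pp)
    participant_data(g$participant_id[1], g$condition[1],
                     pair_id = if (nzchar(g$pair_id[1]) && !is.na(g$pair_id[1]))
                       g$pair_id[1] else NA,
                     records = records, grid = grid)
  })
}

#' Read a trial-log file
#'
#' Reads and validates a canonical trial-log CSV (see [write_trials()]);
#' malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param grid A [grid_spec()].
#' @return Named list of [participant_data()].
#' @export
read_trials <- function(path, grid = grid_spec()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  parse_trials(df, grid, source = path)
}

#' Read an external trial table through a column mapping
#'
#' Adapter for externally deposited trial logs whose column names differ
#' from the canonical schema. `column_mapping` maps canonical names to the
#' external ones; unmapped extra columns are preserved as an `annotations`
#' attribute on each participant.
#'
#' @param path CSV file path.
#' @param column_mapping Named character vector,
#'   `c(canonical = "external_name", ...)`; must cover all canonical
#'   columns.
#' @param grid A [grid_spec()].
#' @return Named list of [participant_data()].
#' @export
map_external_schema <- function(path, column_mapping, grid = grid_spec()) {
  req <- trial_log_columns()
  unmapped <- setdiff(req, names(column_mapping))
  if (length(unmapped)) {
    stop("configuration error: no mapping for required field(s): ",
         paste(unmapped, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_ext <- setdiff(unname(column_mapping[req]), names(df))
  if (length(missing_ext)) {
    stop("configuration error: mapped column(s) absent from file: ",
         paste(missing_ext, collapse = ", "))
  }
  canon <- df[, unname(column_mapping[req]), drop = FALSE]
  names(canon) <- req
  extras <- df[, setdiff(names(df), unname(column_mapping[req])), drop = FALSE]
  out <- parse_trials(canon, grid, source = path)
  if (ncol(extras)) {
    for (id in names(out)) {
      attr(out[[id]], "annotations") <-
        extras[canon$participant_id == id, , drop = FALSE]
    }
  }
  out
}

#' Write a reward landscape to text
#'
#' One row per option (`index`, `row`, `col`, `mean_reward`; 1-based
#' coordinates, 0-based index), preceded by `#`-comment header lines
#' carrying the generative metadata, plus a JSON metadata sidecar
#' (`<path>.json`).
#'
#' @param env A `bandit_env`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  grid <- env$grid
  hdr <- c(sprintf("# lambda=%.10g", env$lambda),
           sprintf("# max_value=%d", env$max_value),
           sprintf("# noise_sd=%.10g", env$noise_sd),
           sprintf("# seed=%s", ifelse(is.na(env$seed), "", env$seed)))
  df <- data.frame(index = 0:(grid$n_options - 1L),
                   row = grid$coords[, "row"] + 1L,
                   col = grid$coords[, "col"] + 1L,
                   mean_reward = env$mean_rewards)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  jsonlite::write_json(
    list(lambda = env$lambda, max_value = env$max_value,
         noise_sd = env$noise_sd,
         seed = if (is.na(env$seed)) NULL else env$seed,
         n_rows = grid$n_rows, n_cols = grid$n_cols),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reward landscape written by [write_environment()]
#'
#' @param path File path.
#' @return A `bandit_env`.
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else ""
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  grid <- grid_spec(max(df$row), max(df$col))
  ord <- order(df$index)
  df <- df[ord, , drop = FALSE]
  structure(
    list(mean_rewards = df$mean_reward,
         max_value = as.integer(meta$max_value),
         lambda = as.numeric(meta$lambda),
         noise_sd = as.numeric(meta$noise_sd),
         seed = if (nzchar(meta$seed %||% "")) as.integer(meta$seed) else NA_integer_,
         grid = grid),
    class = "bandit_env"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration
#'
#' Collects everything a reproducible run depends on: master seed, grid
#' geometry, generative kernel, session/trial counts, model family labels
#' and optimizer settings. Round-trips losslessly through JSON.
#'
#' @param master_seed Integer master seed.
#' @param n_rows,n_cols Grid geometry.
#' @param env_lambda Generative length-scale.
#' @param n_envs,n_trials Experiment size.
#' @param family Character vector of model names to fit.
#' @param de Optimizer settings ([de_settings()]).
#' @param noise_var GP observation-noise variance (scaled scale).
#' @return Object of class `run_config`.
#' @export
run_config <- function(master_seed, n_rows = 11L, n_cols = 15L,
                       env_lambda = 1.5, n_envs = 6L, n_trials = 25L,
                       family = names(default_model_family()),
                       de = de_settings(), noise_var = 1e-4) {
  structure(
    list(master_seed = as.integer(master_seed), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), env_lambda = env_lambda,
         n_envs = as.integer(n_envs), n_trials = as.integer(n_trials),
         family = family, de = de, noise_var = noise_var,
         package_version = as.character(utils::packageVersion("socialbandit"))),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de$n_pop <- x$de$n_pop %||% NULL
  structure(x, class = "run_config")
}
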