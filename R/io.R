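PARAMS_SCHEMA_VERSION <- "1.0"

#' Read a long-format activity table
#'
#' Reads the canonical activity CSV (UTF-8, comma-separated, header
#' mandatory): columns `subject_id`, `t`, `y`, then any number of treatment
#' columns prefixed `x_` and environment columns prefixed `z_`. Each subject
#' must have exactly one row per minute with `t` contiguous from 1 and
#' nonnegative integer counts; malformed rows produce errors citing the
#' offending row numbers (no silent imputation).
#'
#' @param path CSV file path.
#' @return Named list of [activity_series()], one per subject.
#' @export
read_activity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "t", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("activity table is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(is.na(df$y) | df$y < 0 | df$y != floor(df$y))
  if (length(bad) > 0L)
    stop("non-integer or negative activity count at data row(s): ",
         paste(head(bad, 10), collapse = ", "))
  xcols <- grep("^x_", names(df), value = TRUE)
  zcols <- grep("^z_", names(df), value = TRUE)
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    if (any(duplicated(sub$t)))
      stop(sprintf("subject %s: duplicated minute index", sid))
    if (!identical(as.integer(sub$t), seq_len(nrow(sub))))
      stop(sprintf("subject %s: minute index has gaps or does not start at 1", sid))
    out[[as.character(sid)]] <- activity_series(
      sid, sub$y,
      x = if (length(xcols)) as.matrix(sub[xcols]) else NULL,
      z = if (length(zcols)) as.matrix(sub[zcols]) else NULL)
  }
  out
}

#' Write activity series to the long-format CSV
#'
#' @param series_list A list of [activity_series()] (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(series_list, path) {
  if (inherits(series_list, "activity_series")) series_list <- list(series_list)
  tabs <- lapply(series_list, function(s) {
    df <- data.frame(subject_id = s$subject_id, t = s$t, y = s$y)
    if (ncol(s$x) > 0L) {
      x <- s$x; colnames(x) <- paste0("x_", if (is.null(colnames(s$x)))
        seq_len(ncol(s$x)) else colnames(s$x))
      df <- cbind(df, x)
    }
    if (ncol(s$z) > 0L) {
      z <- s$z; colnames(z) <- paste0("z_", if (is.null(colnames(s$z)))
        seq_len(ncol(s$z)) else colnames(s$z))
      df <- cbind(df, z)
    }
    df
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

params_to_list <- function(params, config) {
  list(schema_version = PARAMS_SCHEMA_VERSION,
       M = config$M, D_max = config$D_max,
       duration_family = config$duration_family,
       q = config$q, p = config$p, d = config$d,
       delta = params$delta,
       emission = list(b00 = params$emission$b00, b10 = params$emission$b10,
                       gamma0 = params$emission$gamma0, b0 = params$emission$b0,
                       b1 = params$emission$b1, gamma = params$emission$gamma),
       duration = list(shape = params$duration$shape,
                       scale = params$duration$scale,
                       c = params$duration$c, eta = params$duration$eta),
       transition = list(d_coef = params$transition$d_coef,
                         rho = params$transition$rho))
}

list_to_params <- function(obj) {
  known <- c("schema_version", "M", "D_max", "duration_family", "q", "p", "d",
             "delta", "emission", "duration", "transition",
             "loglik", "n_params", "bic", "converged", "n_restarts_used",
             "gradient_norm", "subject_id", "T")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown field(s) in parameter JSON: ",
            paste(unknown, collapse = ", "))
  if (is.null(obj$schema_version) ||
      !identical(as.character(obj$schema_version), PARAMS_SCHEMA_VERSION))
    stop(sprintf("parameter JSON schema version mismatch: found %s, expected %s",
                 if (is.null(obj$schema_version)) "<none>" else obj$schema_version,
                 PARAMS_SCHEMA_VERSION))
  config <- model_config(M = obj$M, D_max = obj$D_max,
                         duration_family = obj$duration_family,
                         q = obj$q, p = obj$p, d = if (is.null(obj$d)) 0L else obj$d)
  M <- config$M; q <- config$q; p <- config$p
  as_mat <- function(v, nr, nc) {
    if (nr * nc == 0L) return(matrix(0, nr, nc))
    matrix(unlist(v), nr, nc)
  }
  as_arr <- function(v, dims) {
    if (prod(dims) == 0L) return(array(0, dims))
    array(unlist(v), dims)
  }
  params <- subject_parameters(
    delta = as.numeric(obj$delta),
    emission = emission_coefficients(
      b00 = obj$emission$b00,
      b10 = as.numeric(unlist(obj$emission$b10)),
      gamma0 = as.numeric(unlist(obj$emission$gamma0)),
      b0 = as.numeric(obj$emission$b0),
      b1 = as_mat(obj$emission$b1, M, q),
      gamma = as_mat(obj$emission$gamma, M, p)),
    duration = duration_model(
      shape = as.numeric(obj$duration$shape),
      scale = as.numeric(obj$duration$scale),
      c = as_mat(obj$duration$c, M, q),
      eta = as_mat(obj$duration$eta, M, p)),
    transition = transition_coefficients(
      d_coef = as_arr(obj$transition$d_coef, c(M, M, q)),
      rho = as_arr(obj$transition$rho, c(M, M, p))))
  v <- validate_parameters(params, config)
  if (nrow(v) > 0L)
    stop("loaded parameters violate model invariants: ",
         paste(sprintf("[%s] %s", v$code, v$message), collapse = "; "))
  list(params = params, config = config)
}

#' Parameter and fit JSON serialization
#'
#' Lossless (full double precision) schema-versioned JSON round trip for
#' subject parameter sets and fit results. Unknown extra fields are tolerated
#' with a warning; a schema version mismatch or an invariant violation on
#' load is an error.
#'
#' @param params A `"subject_parameters"` object.
#' @param config Its [model_config()].
#' @param path JSON file path.
#' @return `write_parameters_json()` returns `path` invisibly;
#'   `read_parameters_json()` returns `list(params, config)`.
#' @export
write_parameters_json <- function(params, config, path) {
  jsonlite::write_json(params_to_list(params, config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  list_to_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_parameters_json
#' @param fit A `"subject_fit"` object.
#' @export
write_fit_json <- function(fit, path) {
  obj <- params_to_list(fit$params_hat, fit$config)
  obj$subject_id <- fit$subject_id
  obj$loglik <- fit$loglik
  obj$n_params <- fit$n_params
  obj$bic <- fit$bic
  obj$converged <- fit$converged
  obj$n_restarts_used <- fit$n_restarts_used
  obj$gradient_norm <- fit$gradient_norm
  obj$T <- fit$T
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- list_to_params(obj)
  structure(list(subject_id = obj$subject_id, params_hat = pc$params,
                 loglik = obj$loglik, n_params = obj$n_params,
                 bic = obj$bic, converged = obj$converged,
                 n_restarts_used = obj$n_restarts_used,
                 gradient_norm = obj$gradient_norm,
                 M = pc$config$M, T = obj$T, config = pc$config),
            class = "subject_fit")
}

#' Serialize population estimates (with full covariance matrices) to JSON
#'
#' @param pop A `"population_estimates"` object.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_population_json <- function(pop, path) {
  obj <- list(schema_version = PARAMS_SCHEMA_VERSION,
              n = pop$n, responses = pop$responses,
              center = pop$center, center_values = pop$center_values,
              coefficients = pop$coefficients, se = pop$se, vcov = pop$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
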