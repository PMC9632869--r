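#' Write / read a return table as JSON
#'
#' Stores the grid atoms, the (state, action) key index and the
#' probability matrix in a single JSON document.
#'
#' @param eta A `return_table`.
#' @param path Output file.
#' @export
write_return_table <- function(eta, path) {
  obj <- list(atoms = eta$grid$atoms, states = eta$states,
              actions = eta$actions, n_states = nrow(eta$index),
              n_actions = ncol(eta$index), probs = eta$probs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_return_table
#' @return `read_return_table` returns the reconstructed `return_table`.
#' @export
read_return_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  valid <- matrix(FALSE, obj$n_states, obj$n_actions)
  valid[cbind(obj$states, obj$actions)] <- TRUE
  return_table(obj$n_states, valid, support_grid(obj$atoms),
               probs = matrix(unlist(obj$probs), nrow = length(obj$states)))
}

#' Write / read an empirical MDP as JSON
#'
#' @param mdp An `mdp_model`.
#' @param path Output file.
#' @export
write_mdp <- function(mdp, path) {
  obj <- list(n_states = mdp$n_states, n_actions = mdp$n_actions,
              probs = as.numeric(mdp$probs), valid = as.logical(mdp$valid),
              init = mdp$init,
              counts = if (is.null(mdp$counts)) NULL else as.numeric(mdp$counts))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mdp
#' @return `read_mdp` returns the reconstructed `mdp_model`.
#' @export
read_mdp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$n_states; na <- obj$n_actions
  mdp_model(array(obj$probs, dim = c(k, na, k + 2)),
            matrix(obj$valid, k, na), obj$init,
            counts = if (is.null(obj$counts)) NULL
                     else array(obj$counts, dim = c(k, na, k + 2)))
}

#' Write / read a feature matrix as CSV with empty-field missing values
#'
#' @param m Numeric matrix (`NA` = missing).
#' @param path Output file.
#' @export
write_observation_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observation_csv
#' @export
read_observation_csv <- function(path) {
  as.matrix(utils::read.csv(path, na.strings = ""))
}

#' Write / read a trajectory table as CSV
#'
#' The action id is expanded into its intravenous-fluid and vasopressor
#' dose bins (`action = (iv - 1) * n_vaso_bins + vaso`).
#'
#' @param traj Trajectory data frame.
#' @param path Output file.
#' @param n_vaso_bins Vasopressor bins per drug (default 5).
#' @export
write_trajectory_csv <- function(traj, path, n_vaso_bins = 5) {
  out <- traj
  out$action_iv_bin <- (traj$action - 1L) %/% n_vaso_bins + 1L
  out$action_vaso_bin <- (traj$action - 1L) %% n_vaso_bins + 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, n_vaso_bins = 5) {
  df <- utils::read.csv(path)
  if (is.null(df$action) && !is.null(df$action_iv_bin))
    df$action <- (df$action_iv_bin - 1L) * n_vaso_bins + df$action_vaso_bin
  df
}
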