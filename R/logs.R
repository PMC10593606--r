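# Game-log serialization: JSONL (one record per round) and graph exports.

#' Write a game log as JSONL
#'
#' One JSON object per line per round with fields `round_t`, `actions`,
#' `payoffs`, `capital`, `recs` (pair, valence, the two accept decisions,
#' executed flag), and `edges_after`; a header line carries the
#' configuration, seed and initial edge list.
#'
#' @param log A `coop_log`.
#' @param path Output path.
#' @export
write_game_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "header",
                 config = log$config[c("n_players", "n_rounds", "cost",
                                       "benefit", "accept_rule_add",
                                       "accept_rule_delete")],
                 seed = log$seed,
                 initial_edges = edges_to_list(log$initial_edges))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (r in log$records) {
    rec <- list(type = "round", round_t = r$round_t, actions = r$actions,
                payoffs = r$payoffs, capital = r$capital,
                recs = r$recs, edges_after = edges_to_list(r$edges_after))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), con)
  }
  invisible(path)
}

edges_to_list <- function(e) {
  if (is.null(e) || length(e) == 0) return(matrix(integer(), 0, 2))
  matrix(as.integer(e), ncol = 2, dimnames = NULL)
}

#' Read a JSONL game log
#'
#' @param path Path written by [write_game_log()].
#' @return A `coop_log`.
#' @export
read_game_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  assert_that(identical(header$type, "header"), "missing log header line")
  cfg <- do.call(game_config, c(header$config[c("n_players", "n_rounds",
                                                "cost", "benefit")],
                                list(accept_rule_add = header$config$accept_rule_add,
                                     accept_rule_delete = header$config$accept_rule_delete)))
  records <- lapply(lines[-1], function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    recs <- as.data.frame(r$recs)
    if (nrow(recs) == 0) {
      recs <- data.frame(i = integer(), j = integer(), valence = character(),
                         accept_i = logical(), accept_j = logical(),
                         executed = logical())
    }
    list(round_t = r$round_t, actions = as.integer(r$actions),
         payoffs = as.numeric(r$payoffs), capital = as.numeric(r$capital),
         recs = recs, edges_after = edges_to_list(r$edges_after))
  })
  structure(list(config = cfg, seed = header$seed,
                 initial_edges = edges_to_list(header$initial_edges),
                 records = records),
            class = "coop_log")
}

#' Export the per-round graphs of a log
#'
#' Writes one CSV edge list per round (columns `i`, `j`), and optionally
#' GraphML, into a directory.
#'
#' @param log A `coop_log`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"graphml"`, or both.
#' @export
export_graphs <- function(log, dir, format = c("csv", "graphml")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- log$config$n_players
  for (t in seq_along(log$records)) {
    e <- log$records[[t]]$edges_after
    if ("csv" %in% format) {
      utils::write.csv(data.frame(i = e[, 1], j = e[, 2]),
                       file.path(dir, sprintf("round_%02d.csv", t)),
                       row.names = FALSE)
    }
    if ("graphml" %in% format) {
      g <- igraph::graph_from_edgelist(edges_to_list(e), directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
      igraph::write_graph(g, file.path(dir, sprintf("round_%02d.graphml", t)),
                          format = "graphml")
    }
  }
  invisible(dir)
}
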