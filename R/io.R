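# File I/O: networks as commented edge lists or GraphML, time series as
# CSV with a seed/config header, summaries as JSON, and a tiny logging
# helper.  Every output file carries the seed and a config hash so runs can
# be regenerated from their metadata.

#' Write / read a network
#'
#' Edge-list format: `#`-comment header lines carry per-node types and
#' states (`# types: ABBA...`, `# states: SIS...`), then one edge per line,
#' whitespace-delimited, 0-based ids, smaller id first.  GraphML (via
#' igraph) stores `type` ("A"/"B") and `state` ("S"/"I") node attributes.
#'
#' @param net a [network_state()].
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param header named character vector of extra `# key: value` comment
#'   lines (edge-list format only).
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   [network_state()].
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml"),
                          header = character()) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, net$n_nodes - igraph::vcount(g)))
    igraph::V(g)$type <- c("A", "B")[net$type]
    igraph::V(g)$state <- if (is.null(net$state)) NA_character_ else
      c("S", "I")[net$state + 1L]
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  lines <- c(sprintf("# n_nodes: %d", net$n_nodes),
             sprintf("# types: %s", paste(c("A", "B")[net$type],
                                          collapse = "")))
  if (!is.null(net$state))
    lines <- c(lines, sprintf("# states: %s",
                              paste(c("S", "I")[net$state + 1L],
                                    collapse = "")))
  if (length(header))
    lines <- c(lines, sprintf("# %s: %s", names(header), header))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  if (nrow(net$edges))
    writeLines(sprintf("%d %d", net$edges[, 1] - 1L, net$edges[, 2] - 1L),
               con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    type <- match(igraph::V(g)$type, c("A", "B"))
    state_chr <- igraph::V(g)$state
    state <- if (all(is.na(state_chr))) NULL else
      match(state_chr, c("S", "I")) - 1L
    return(network_state(igraph::as_edgelist(g, names = FALSE),
                         type, state, n_nodes = igraph::vcount(g)))
  }
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  hdr <- lines[is_comment]
  get_field <- function(key) {
    hit <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", hit[1]))
  }
  n_nodes <- as.integer(get_field("n_nodes"))
  types <- get_field("types")
  if (is.null(n_nodes) || is.null(types))
    stop("edge-list header must carry '# n_nodes:' and '# types:' lines",
         call. = FALSE)
  type <- match(strsplit(types, "")[[1]], c("A", "B"))
  states <- get_field("states")
  state <- if (is.null(states)) NULL else
    match(strsplit(states, "")[[1]], c("S", "I")) - 1L
  body <- lines[!is_comment & nzchar(trimws(lines))]
  edges <- if (!length(body)) matrix(integer(), ncol = 2) else {
    parsed <- lapply(seq_along(body), function(i) {
      v <- suppressWarnings(as.integer(strsplit(trimws(body[i]),
                                                "[[:space:]]+")[[1]]))
      if (length(v) != 2L || anyNA(v))
        stop("malformed edge at line ", which(!is_comment)[i], ": '",
             body[i], "'", call. = FALSE)
      v
    })
    do.call(rbind, parsed) + 1L
  }
  network_state(edges, type, state, n_nodes = n_nodes)
}

#' Write a simulation time series as CSV
#'
#' @param ts time-series data.frame (e.g. `gillespie_run(...)$ts`).
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param config optional configuration list; its [config_hash()] is
#'   recorded in the header.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  write.csv(ts, con, row.names = FALSE)
  invisible(path)
}

#' Order-insensitive hash of a configuration list
#'
#' Canonicalizes the list (recursively sorted by name) to JSON and hashes
#' it with a pair of polynomial rolling hashes modulo Mersenne-scale
#' primes, so the hash is stable under key reordering.
#'
#' @param config a (possibly nested) named list.
#' @return a 16-character hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  s <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h1 <- 2166136261 %% 2147483647
  h2 <- 16777619
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b * 17 + 1) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Minimal run logger
#'
#' Opens (and creates) a log file under `out_dir`, echoes messages to the
#' console, and records the run metadata (parameters, seed, package
#' version, timestamp) up front.  Fails early when `out_dir` is not
#' writable.
#'
#' @param out_dir output directory (created if needed).
#' @param config configuration list recorded in the preamble.
#' @param seed seed recorded in the preamble.
#' @param echo also print log lines to the console.
#' @return a function `log(fmt, ...)` writing one line; attribute `path`
#'   holds the log-file location.
#' @export
configure_logging <- function(out_dir, config = NULL, seed = NA,
                              echo = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  path <- file.path(out_dir, "run.log")
  logger <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = path, append = TRUE, sep = "")
    if (echo) message(line)
    invisible(line)
  }
  logger("run start; seed: %s; package: adaptivesis %s", seed,
         as.character(utils::packageVersion("adaptivesis")))
  if (!is.null(config))
    logger("config hash: %s", config_hash(config))
  attr(logger, "path") <- path
  logger
}
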