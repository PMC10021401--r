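#' Build a synthetic county adjacency graph
#'
#' Constructs a connected, undirected neighbour structure for `n_counties`
#' synthetic counties, standing in for a county border map. Counties are
#' placed on a jittered square grid; each is joined to its `k` nearest
#' neighbours (symmetrised), and any remaining components are connected
#' through their closest cross-component pair. The result is deterministic
#' given `seed`.
#'
#' @param n_counties Number of counties (>= 2).
#' @param seed Integer seed controlling the jitter.
#' @param k Nearest-neighbour count before symmetrisation (default 2).
#'
#' @return An object of class `"county_adjacency"`: a list with elements
#'   `n` (node count), `edges` (two-column integer matrix of 1-based
#'   county ids, each edge once with `i < j`), and `nbr` (list of
#'   neighbour id vectors per county).
#' @export
make_adjacency <- function(n_counties, seed = 1L, k = 2L) {
  if (!is.numeric(n_counties) || length(n_counties) != 1 || n_counties < 2) {
    stop("`n_counties` must be a single number >= 2", call. = FALSE)
  }
  n <- as.integer(n_counties)
  if (n == 2L) {
    return(new_adjacency(2L, matrix(c(1L, 2L), nrow = 1)))
  }
  side <- ceiling(sqrt(n))
  pts <- cbind((seq_len(n) - 1L) %% side, (seq_len(n) - 1L) %/% side)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pts <- pts + matrix(stats::runif(2L * n, -0.35, 0.35), ncol = 2)

  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  k <- min(as.integer(k), n - 1L)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    cbind(pmin(i, nn), pmax(i, nn))
  }))
  edges <- unique(edges)

  # join components until connected (closest pair across the split)
  repeat {
    comp <- components_of(n, edges)
    if (max(comp) == 1L) break
    in1 <- which(comp == 1L)
    out1 <- which(comp != 1L)
    sub <- d[in1, out1, drop = FALSE]
    hit <- arrayInd(which.min(sub), dim(sub))
    i <- in1[hit[1]]; j <- out1[hit[2]]
    edges <- rbind(edges, c(min(i, j), max(i, j)))
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  new_adjacency(n, edges)
}

new_adjacency <- function(n, edges) {
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  nbr <- lapply(seq_len(n), function(i) {
    sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  })
  structure(list(n = n, edges = edges, nbr = nbr),
            class = "county_adjacency")
}

# connected-component labels by label propagation over the edge list
components_of <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    a <- pmin(comp[edges[, 1]], comp[edges[, 2]])
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' @export
print.county_adjacency <- function(x, ...) {
  cat("county adjacency graph:", x$n, "counties,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write / read an adjacency edge list
#'
#' Plain whitespace-delimited edge list with 0-based county ids, one edge
#' per line, preceded by a `# schema:` comment line.
#'
#' @param adjacency A `"county_adjacency"` object.
#' @param path File path.
#' @return `write_adjacency` returns `path` invisibly; `read_adjacency`
#'   returns a `"county_adjacency"`.
#' @export
write_adjacency <- function(adjacency, path) {
  stopifnot(inherits(adjacency, "county_adjacency"))
  lines <- c("# schema: u5mproj/adjacency v1",
             sprintf("%d %d", adjacency$edges[, 1] - 1L, adjacency$edges[, 2] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer)) + 1L
  edges <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  new_adjacency(max(edges), edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Scoped RNG helpers: run under a given seed without disturbing the
# caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
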