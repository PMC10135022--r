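# Independent reference implementations used as oracles. Each is coded
# from the textbook definition, separately from the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_peptide_set <- function(n, len_range = c(8, 45), prefix = "p") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  peptide_set(sprintf("%s%03d", prefix, seq_len(n)),
              vapply(lens, random_peptide, character(1)))
}

# --- brute-force half-space proximal test --------------------------------
# For each node u, walk the candidate list: take the closest remaining
# candidate v (first index on ties), record the edge, then drop v and all
# candidates strictly closer to v than to u. Returns a sorted two-column
# matrix of undirected edges (i < j, integer indices).
hsp_oracle_edges <- function(dm) {
  n <- nrow(dm)
  edges <- matrix(integer(0), ncol = 2)
  for (u in 1:n) {
    alive <- rep(TRUE, n)
    alive[u] <- FALSE
    while (any(alive)) {
      cand <- which(alive)
      dists <- dm[u, cand]
      v <- cand[order(dists, cand)[1]]
      e <- sort(c(u, v))
      edges <- rbind(edges, e)
      for (w in cand) {
        if (w != v && dm[w, v] < dm[w, u]) alive[w] <- FALSE
      }
      alive[v] <- FALSE
    }
  }
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  edges
}

edge_matrix_of <- function(net) {
  # integer edge matrix (i < j) of an hsp_network, sorted
  idx_from <- match(net$edges$from, net$node_ids)
  idx_to <- match(net$edges$to, net$node_ids)
  e <- cbind(pmin(idx_from, idx_to), pmax(idx_from, idx_to))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# --- textbook affine-gap Smith-Waterman with canonical traceback ---------
# Same operation contract as the package (first maximal cell in row-major
# order; diagonal > vertical > horizontal; close gaps as early as
# possible; identity = identical aligned positions over the shorter
# sequence length), coded independently as plain-R dynamic programming.
sw_oracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]]
      X[i, j] <- max(H[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(H[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      H[i, j] <- max(0, M[i, j], X[i, j], Y[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(list(score = 0, identity = 0))
  i <- bi; j <- bj; state <- "H"; matches <- 0; len <- 0
  repeat {
    if (state == "H") {
      if (H[i, j] == 0) break
      state <- if (H[i, j] == M[i, j]) "M"
               else if (H[i, j] == X[i, j]) "X" else "Y"
    } else if (state == "M") {
      len <- len + 1
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1; state <- "H"
    } else if (state == "X") {
      len <- len + 1
      close <- X[i, j] == H[i - 1, j] - open - ext
      i <- i - 1
      state <- if (close) "H" else "X"
    } else {
      len <- len + 1
      close <- Y[i, j] == H[i, j - 1] - open - ext
      j <- j - 1
      state <- if (close) "H" else "Y"
    }
  }
  list(score = best, identity = matches / min(n, m), columns = len)
}

# --- betweenness by explicit shortest-path enumeration -------------------
# For every unordered source/target pair: BFS builds the predecessor DAG,
# all shortest paths are enumerated recursively, and each interior vertex
# receives its fraction of the pair's paths. Feasible for n <= 12.
betweenness_oracle <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  enumerate_paths <- function(preds, v, s) {
    if (v == s) return(list(s))
    out <- list()
    for (p in preds[[v]]) {
      for (path in enumerate_paths(preds, p, s)) {
        out[[length(out) + 1L]] <- c(path, v)
      }
    }
    out
  }
  for (s in 1:(n - 1)) {
    # BFS from s
    dist <- rep(Inf, n); dist[s] <- 0
    preds <- vector("list", n)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- union(preds[[w]], v)
      }
    }
    for (t in (s + 1):n) {
      if (is.infinite(dist[t])) next
      paths <- enumerate_paths(preds, t, s)
      for (path in paths) {
        interior <- setdiff(path, c(s, t))
        for (v in interior) btw[v] <- btw[v] + 1 / length(paths)
      }
    }
  }
  btw
}

adj_list_of <- function(ig) {
  lapply(igraph::as_adj_list(ig), as.integer)
}

# tiny helper: peptide_set from bare sequences
pset <- function(seqs, prefix = "p") {
  peptide_set(paste0(prefix, seq_along(seqs)), seqs)
}

# distance/similarity pair from a coordinate matrix (tests build small
# geometric instances directly)
geom_matrices <- function(coords, ids = NULL) {
  ids <- ids %||% paste0("n", seq_len(nrow(coords)))
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(ids, ids)
  dm <- structure(list(ids = ids, values = d), class = "distance_matrix")
  list(d = dm, s = to_similarity(dm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blosum62_tab <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
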