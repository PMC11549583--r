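# independent brute-force oracles, deliberately naive

# connected components by label propagation to fixpoint
oracle_components <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0L)
  lab <- seq_len(n)
  repeat {
    new <- lab
    for (i in seq_len(n)) {
      nb <- which(A[i, ] == 1)
      if (length(nb) > 0) new[i] <- min(new[i], lab[nb])
    }
    if (all(new == lab)) break
    lab <- new
  }
  length(unique(lab))
}

# normalized betweenness by exhaustive simple-path enumeration per pair
oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n <= 2) return(rep(0, n))
  score <- rep(0, n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      best_len <- Inf
      best_paths <- list()
      rec <- function(v, visited, path) {
        if (v == t) {
          if (length(path) < best_len) {
            best_len <<- length(path)
            best_paths <<- list(path)
          } else if (length(path) == best_len) {
            best_paths[[length(best_paths) + 1]] <<- path
          }
          return(invisible())
        }
        if (length(path) >= best_len) return(invisible())
        for (w in which(A[v, ] == 1)) {
          if (!visited[w]) {
            visited[w] <- TRUE
            rec(w, visited, c(path, w))
            visited[w] <- FALSE
          }
        }
      }
      vis <- rep(FALSE, n)
      vis[s] <- TRUE
      rec(s, vis, s)
      if (length(best_paths) == 0) next  # unreachable pair contributes 0
      sigma <- length(best_paths)
      interior <- unlist(lapply(best_paths, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        score[idx] <- score[idx] + as.numeric(tab) / sigma
      }
    }
  }
  score / choose(n - 1, 2)
}

# per-alter assortativity by explicit neighbour-set enumeration
oracle_assortativity <- function(A, vacc) {
  n <- nrow(A)
  known <- which(!is.na(vacc))
  vapply(seq_len(n), function(i) {
    nbk <- intersect(which(A[i, ] == 1), known)
    others <- setdiff(known, i)
    if (length(known) < 2 || length(nbk) == 0 || length(others) == 0) {
      return(NA_real_)
    }
    mean(vacc[nbk]) - mean(vacc[others])
  }, numeric(1))
}

# media category from first principles (independent of categorize_media)
oracle_media <- function(sources) {
  trad <- intersect(sources, c("central_tv", "local_press"))
  onl <- intersect(sources,
                   c("search_engines", "social_media", "influencers"))
  if (length(sources) == 0) NA_character_
  else if (length(trad) > 0 && length(onl) > 0) "both"
  else if (length(trad) > 0) "traditional"
  else "online"
}
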