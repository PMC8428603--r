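# Independent oracles and random-instance generators. These deliberately use
# naive algorithms (full sorts, O(N^2) loops, raw set algebra on pair keys)
# so they share no code with the implementation they check.

random_contact_map <- function(L, n, scores = NULL) {
  pairs <- expand.grid(i = seq_len(L), j = seq_len(L))
  pairs <- pairs[pairs$i < pairs$j, ]
  pick <- pairs[sample(nrow(pairs), min(n, nrow(pairs))), ]
  if (is.null(scores)) scores <- stats::runif(nrow(pick))
  contact_map(data.frame(i = pick$i, j = pick$j, score = scores),
              seq_length = L)
}

pair_keys <- function(map) paste(map$i, map$j)

# three-way partition by raw set algebra
oracle_partition <- function(p_keys, m_keys) {
  list(matched = sort(intersect(p_keys, m_keys)),
       model_only = sort(setdiff(m_keys, p_keys)),
       predicted_only = sort(setdiff(p_keys, m_keys)))
}

# all-pairs distance loop, no vectorized dist()
brute_force_contacts <- function(coords, cutoff, min_sep = 0) {
  n <- nrow(coords)
  out <- NULL
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- sqrt(sum((c(coords$x[a], coords$y[a], coords$z[a]) -
                     c(coords$x[b], coords$y[b], coords$z[b]))^2))
      if (d <= cutoff && abs(coords$pos[a] - coords$pos[b]) >= min_sep) {
        out <- rbind(out, c(min(coords$pos[a], coords$pos[b]),
                            max(coords$pos[a], coords$pos[b])))
      }
    }
  }
  if (is.null(out)) return(character())
  sort(paste(out[, 1], out[, 2]))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_coords <- function(n, spread = 15) {
  tibble::tibble(pos = seq_len(n),
                 x = stats::runif(n, 0, spread),
                 y = stats::runif(n, 0, spread),
                 z = stats::runif(n, 0, spread))
}

# contacts only, shorn of class and bookkeeping attributes
map_tbl <- function(m) tibble::tibble(i = m$i, j = m$j, score = m$score)
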