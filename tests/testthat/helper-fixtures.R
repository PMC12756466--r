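# shared fixture builders and independent oracles

# binary disk mask in an n x m field, 1-based center (cr, cc)
disk_mask <- function(n, m = n, cr, cc, r) {
  rows <- matrix(seq_len(n), n, m)
  cols <- matrix(seq_len(m), n, m, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

img8 <- function(pixels, label = "x") channel_image(pixels, 255, label)

# independent 4-connected flood-fill labeling (BFS), labels in column-major
# first-appearance order
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- c + d[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          idx <- (cc - 1L) * nr + rr
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- nextlab
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  lab
}

# renumber labels in column-major first-appearance order (canonical form)
canonical_labels <- function(lab) {
  u <- unique(lab[lab > 0L])
  map <- integer(max(c(u, 1L)))
  map[u] <- seq_along(u)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# match detected nucleus records to planted truth by nearest centroid
match_to_truth <- function(rec, truth, max_dist = 4) {
  idx <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    d <- sqrt((truth$row - rec$centroid_row[i])^2 +
              (truth$col - rec$centroid_col[i])^2)
    j <- which.min(d)
    idx[i] <- if (d[j] <= max_dist) j else NA_integer_
  }
  idx
}

# planted nucleus count of the spheroid nearest to a segmented ROI
planted_count_for_roi <- function(roi, truth) {
  d <- sqrt((truth$spheroids$row - roi$centroid[1])^2 +
            (truth$spheroids$col - roi$centroid[2])^2)
  sum(truth$nuclei$spheroid_id == which.min(d))
}
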