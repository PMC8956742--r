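# shared fixtures and independent reference implementations

rand_grid <- function(nr = 8, nc = 8, seed = 1, cell_size = 30,
                      origin = c(0, 1000), na_frac = 0) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  if (na_frac > 0) m[sample(nr * nc, round(na_frac * nr * nc))] <- NA
  ev_grid(m, cell_size = cell_size, origin = origin)
}

rand_cat_grid <- function(nr = 10, nc = 10, codes = 1:4, seed = 1,
                          cell_size = 30) {
  set.seed(seed)
  ev_grid(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
          cell_size = cell_size)
}

# independent queue-based flood fill (reference for label_patches)
flood_fill_labels <- function(vals, mask, connectivity = 8) {
  nr <- nrow(vals); nc <- ncol(vals)
  lab <- matrix(NA_integer_, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || !is.na(lab[r0, c0])) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        r <- p[1] + nb[i, 1]; c <- p[2] + nb[i, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] &&
            is.na(lab[r, c]) && vals[r, c] == vals[p[1], p[2]]) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# partitions agree iff labels are a relabeling of each other
same_partition <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!identical(which(is.na(a)), which(is.na(b)))) return(FALSE)
  key <- paste(a[ok], b[ok])
  length(unique(key)) == length(unique(a[ok])) &&
    length(unique(key)) == length(unique(b[ok]))
}

# direct-sum IDW reference, one cell at a time
idw_reference <- function(stations, template, power = 2) {
  pts <- stations$points
  ctr <- cell_centers(template)
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    d <- sqrt((ctr$x[r, c] - pts$x)^2 + (ctr$y[r, c] - pts$y)^2)
    if (any(d == 0)) out[r, c] <- pts$value[which(d == 0)[1]]
    else {
      w <- d^(-power)
      out[r, c] <- sum(w * pts$value) / sum(w)
    }
  }
  out
}

# exhaustive optimal 1-D partition: minimal within-class SS over all
# contiguous splits of the sorted values
exhaustive_jenks_ss <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ss <- function(x) sum((x - mean(x))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ss(v[(cuts[i] + 1):cuts[i + 1]])
    if (tot < best) best <- tot
  }
  best
}

jenks_ss_of_breaks <- function(values, breaks) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1
  sum(tapply(values, cls, function(x) sum((x - mean(x))^2)))
}

tiny_scenario_config <- function(seed = 1, rows = 60, cols = 60, ...) {
  scenario_config(rows = rows, cols = cols, seed = seed, ...)
}
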