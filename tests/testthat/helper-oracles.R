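# Independent, straightforwardly-coded oracles used to check the package's
# implementations on small instances. They deliberately share no code with
# the package internals.

# plain-R GrowCut: literal synchronous transcription of the conquest rule,
# the attenuation weight and the label-change counter
oracle_growcut <- function(image, seeds, max_iters = 10000) {
  h <- nrow(image)
  w <- ncol(image)
  lab <- matrix(0L, h, w)
  str <- matrix(0, h, w)
  chg <- matrix(0L, h, w)
  for (i in seq_len(nrow(seeds))) {
    lab[seeds$y[i] + 1, seeds$x[i] + 1] <-
      if (seeds$label[i] == "foreground") 2L else 1L
    str[seeds$y[i] + 1, seeds$x[i] + 1] <- 1
  }
  maxd <- max(image) - min(image)
  g <- function(a, b) {
    if (maxd == 0) return(1)
    max(0, min(1, 1 - abs(a - b) / maxd))
  }
  nbhd <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  for (it in seq_len(max_iters)) {
    lab2 <- lab
    str2 <- str
    changed <- FALSE
    for (yy in 1:h) {
      for (xx in 1:w) {
        best_s <- str[yy, xx]
        best_l <- lab[yy, xx]
        conq <- FALSE
        for (d in nbhd) {
          ny <- yy + d[1]
          nx <- xx + d[2]
          if (ny < 1 || ny > h || nx < 1 || nx > w) next
          if (lab[ny, nx] == 0L) next
          atk <- str[ny, nx] * g(image[yy, xx], image[ny, nx])
          if (atk > best_s) {
            best_s <- atk
            best_l <- lab[ny, nx]
            conq <- TRUE
          }
        }
        if (conq) {
          changed <- TRUE
          if (best_l != lab[yy, xx]) chg[yy, xx] <- chg[yy, xx] + 1L
          lab2[yy, xx] <- best_l
          str2[yy, xx] <- best_s
        }
      }
    }
    lab <- lab2
    str <- str2
    if (!changed) break
  }
  list(label = lab, strength = str, changes = chg)
}

# box-counting estimate of the boundary's fractal dimension
oracle_box_dimension <- function(mask) {
  shifted <- function(m, dy, dx) {
    h <- nrow(m)
    w <- ncol(m)
    out <- matrix(FALSE, h, w)
    ys <- pmin(pmax(1:h + dy, 1), h)
    xs <- pmin(pmax(1:w + dx, 1), w)
    m[ys, xs]
  }
  interior <- shifted(mask, 1, 0) & shifted(mask, -1, 0) &
    shifted(mask, 0, 1) & shifted(mask, 0, -1)
  boundary <- which(mask & !interior, arr.ind = TRUE)
  sizes <- c(1, 2, 4, 8)
  counts <- vapply(sizes, function(s) {
    length(unique(paste((boundary[, 1] - 1) %/% s,
                        (boundary[, 2] - 1) %/% s)))
  }, numeric(1))
  -unname(coef(lm(log(counts) ~ log(sizes)))[2])
}

# Rand index by explicit iteration over all element pairs
oracle_rand_index <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  n <- length(a)
  agree <- 0
  total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / total
}

# AUC by exhaustive counting over all positive/negative pairs
oracle_auc <- function(scores, ref) {
  pos <- scores[as.logical(ref)]
  neg <- scores[!as.logical(ref)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# greedy influence-map selection by repeated argmax with an exclusion zone
oracle_greedy_select <- function(map, j, min_sep) {
  h <- nrow(map)
  w <- ncol(map)
  avail <- matrix(TRUE, h, w)
  picks <- NULL
  for (k in seq_len(j)) {
    if (!any(avail)) break
    best <- -Inf
    bx <- by <- NA
    # scan in row-major order so ties go to the first such pixel
    for (y in 0:(h - 1)) {
      for (x in 0:(w - 1)) {
        if (avail[y + 1, x + 1] && map[y + 1, x + 1] > best) {
          best <- map[y + 1, x + 1]
          bx <- x
          by <- y
        }
      }
    }
    picks <- rbind(picks, c(bx, by))
    for (y in 0:(h - 1)) {
      for (x in 0:(w - 1)) {
        if (max(abs(x - bx), abs(y - by)) < min_sep) {
          avail[y + 1, x + 1] <- FALSE
        }
      }
    }
  }
  picks
}

# two-region piecewise-constant test image: a bright interior rectangle on a
# dark background (perfectly separable: the transition weight across the
# boundary is zero)
two_region_fixture <- function(w = 16, h = 16, lo = 0.1, hi = 0.9) {
  image <- matrix(lo, h, w)
  mask <- matrix(FALSE, h, w)
  y0 <- floor(h / 4) + 1
  y1 <- ceiling(3 * h / 4)
  x0 <- floor(w / 4) + 1
  x1 <- ceiling(3 * w / 4)
  mask[y0:y1, x0:x1] <- TRUE
  image[mask] <- hi
  list(image = image, mask = mask)
}
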