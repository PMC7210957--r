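# Small internal helpers shared across modules.

.clip01 <- function(x) {   # keeps dim attributes, unlike pmin/pmax(0, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

.log_msg <- function(...) {
  if (isTRUE(getOption("SeqIsoTrim.verbose", FALSE)))
    message(sprintf(...))
  invisible(NULL)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("zero-length vector cannot be normalized")
  v / n
}

# Rodrigues rotation matrix: angle (rad) about unit axis
.rot_axis <- function(axis, angle) {
  a <- .unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal rotation taking unit vector u onto unit vector v
.rot_between <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    ax <- if (abs(u[1]) < 0.9) .unit(pracma_cross(u, c(1, 0, 0)))
          else .unit(pracma_cross(u, c(0, 1, 0)))
    return(.rot_axis(ax, pi))
  }
  ax <- pracma_cross(u, v)
  s <- sqrt(sum(ax^2))
  .rot_axis(ax / s, atan2(s, c_))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# quasi-uniform unit directions (Fibonacci sphere), optionally randomly
# rotated using the current RNG state
.fibonacci_sphere <- function(n, rotate = TRUE) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  d <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  if (rotate) {
    # random rotation from three uniform angles
    R <- .rot_axis(c(0, 0, 1), runif(1, 0, 2 * pi)) %*%
         .rot_axis(c(0, 1, 0), acos(runif(1, -1, 1))) %*%
         .rot_axis(c(1, 0, 0), runif(1, 0, 2 * pi))
    d <- d %*% t(R)
  }
  d
}

# connected components (26-connectivity) of a sparse logical 3D mask;
# returns an integer array with 0 outside and component ids inside
.mask_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  out <- array(0L, d)
  if (!length(idx)) return(out)
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1) + d[1] * ((pos[, 2] - 1) + d[2] * (pos[, 3] - 1))
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, offs[o, ], "+")
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
          np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nk <- (np[ok, 1] - 1) + d[1] * ((np[ok, 2] - 1) + d[2] * (np[ok, 3] - 1))
    ii <- which(ok)
    for (j in seq_along(nk)) {
      other <- lookup[[as.character(nk[j])]]
      if (!is.null(other)) {
        ra <- find(ii[j]); rb <- find(other)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  out[idx] <- as.integer(factor(roots))
  out
}

# canonical JSON + md5 for manifests
.hash_obj <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
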