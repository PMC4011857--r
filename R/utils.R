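# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 26-connected component labelling of a voxel set (n x 3 index matrix).
# Returns an integer label per voxel, 1..k, ordered by decreasing size.
label_components <- function(voxels, connectivity = 26) {
  voxels <- as_voxel_matrix(voxels)
  n <- nrow(voxels)
  if (n == 0L) return(integer(0))
  lo <- apply(voxels, 2, min) - 1L
  d <- as.integer(apply(voxels, 2, max) - lo + 2L)
  shifted <- sweep(voxels, 2, lo - 1L)
  lin <- voxel_linear(shifted, d)
  slot <- integer(prod(d))     # maps linear index -> row number
  slot[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  off_lin <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    labels[i] <- cur
    while (length(frontier)) {
      nb <- outer(lin[frontier], off_lin, "+")
      rows <- slot[nb]
      rows <- unique(rows[rows > 0L])
      rows <- rows[labels[rows] == 0L]
      labels[rows] <- cur
      frontier <- rows
    }
  }
  sizes <- tabulate(labels, cur)
  rank <- integer(cur)
  rank[order(sizes, decreasing = TRUE)] <- seq_len(cur)
  rank[labels]
}
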