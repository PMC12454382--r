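## 8-connected component labelling on binary masks (EBImage::bwlabel is
## 4-connected, so neighbour adjacency is assembled here and the components
## are found with igraph).

## mask: logical matrix. Returns an integer matrix of labels (0 background),
## numbered in row-major order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r <- ((idx - 1L) %% h) + 1L
    c <- ((idx - 1L) %/% h) + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- mask[nb]
    from <- c(from, idx[ok][hit])
    to <- c(to, nb[hit])
  }
  vid <- match(seq_len(h * w), idx)          # linear index -> vertex id
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
  memb <- igraph::components(g)$membership
  ## renumber components by row-major order of their first pixel
  rowmajor <- ((idx - 1L) %% h) * w + ((idx - 1L) %/% h)  # row-major rank
  first <- tapply(rowmajor, memb, min)
  renum <- match(memb, as.integer(names(sort(first))))
  lab[idx] <- renum
  lab
}

## Largest component of a logical mask; ties by smallest row-major first
## pixel (which is the lowest label after renumbering).
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))[1]
  lab == best
}
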