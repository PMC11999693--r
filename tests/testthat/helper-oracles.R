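# Brute-force threshold-sum TFCE oracle (igraph connected components),
# independent of the compiled implementation.
tfce_oracle <- function(stat, H, E, dh, connectivity = 6) {
  d <- dim(stat)
  out <- array(0, d)
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  coords <- arrayInd(seq_len(prod(d)), d)
  for (h in dh * seq_len(floor(hmax / dh + 1e-9))) {
    sup <- which(stat >= h)
    if (!length(sup)) next
    pos <- coords[sup, , drop = FALSE]
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    lookup <- stats::setNames(seq_along(sup), key(pos))
    edges <- c()
    for (dirn in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      nb <- sweep(pos, 2, dirn, `+`)
      hit <- lookup[key(nb)]
      ok <- !is.na(hit)
      edges <- c(edges, rbind(which(ok), unname(hit[ok])))
    }
    g <- igraph::make_empty_graph(n = length(sup), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    ext <- comp$csize[comp$membership]
    out[sup] <- out[sup] + ext^E * h^H * dh
  }
  out
}
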