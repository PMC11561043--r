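# Random structures shared by the property-style and acceptance tests.

# Random property graphs exercising id characters, payloads and CSV
# escaping.
random_graph <- function(seed) {
  set.seed(seed)
  n <- sample(2:12, 1)
  labels <- sample(c("Structure", "ProteinChain", "Domain", "BoundEntity",
                     "CognateLigand", "EC"), n, replace = TRUE)
  rand_str <- function(k) paste(sample(c(letters, LETTERS, 0:9, ",", '"',
                                         " ", ":", ";", "'"), k,
                                       replace = TRUE), collapse = "")
  ids <- paste0("n", seq_len(n), ":", vapply(rep(4, n), rand_str,
                                             character(1)))
  props <- lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(stats::setNames(character(0), character(0)))
    keys <- sort(sample(c("alpha", "beta", "gamma", "delta"), k))
    stats::setNames(vapply(rep(6, k), rand_str, character(1)), keys)
  })
  nodes <- tibble::tibble(node_id = ids, label = labels, properties = props)
  ne <- sample(1:15, 1)
  edges <- tibble::tibble(
    start_id = sample(ids, ne, replace = TRUE),
    end_id = sample(ids, ne, replace = TRUE),
    type = sample(c("CONTAINS", "HAS_DOMAIN", "INTERACTS_WITH",
                    "MAPS_TO", "IN_EC_CLASS"), ne, replace = TRUE),
    properties = lapply(seq_len(ne), function(i) {
      stats::setNames(rand_str(5), "payload")
    }))
  nodes <- nodes[!duplicated(nodes$node_id), ]
  nodes <- dplyr::arrange(nodes, node_id)
  edges <- dplyr::arrange(edges, type, start_id, end_id)
  structure(list(nodes = nodes, edges = edges), class = "cogmap_graph")
}

# Blob fingerprints: `k` prototypes in well-separated key regions, each
# member flipping a couple of bits at random.
blob_fingerprints <- function(n_per, k, seed) {
  set.seed(seed)
  protos <- lapply(seq_len(k), function(i) {
    v <- integer(166)
    v[((i - 1) * 30 + 1):((i - 1) * 30 + 22)] <- 1L
    v
  })
  fps <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(n_per)) {
      v <- protos[[i]]
      flip <- sample.int(166, 2)
      v[flip] <- 1L - v[flip]
      fps[[sprintf("blob%d_%02d", i, j)]] <- v
    }
  }
  fps
}
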