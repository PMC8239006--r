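## shared fixtures: all built in code, nothing on disk

## Y-shaped tree: 50-um trunk, two 50-um children, 10-um segments
y_tree <- function() {
  seg <- function(parent, x0, y0, x1, y1)
    data.frame(parent = parent, length = sqrt((x1 - x0)^2 + (y1 - y0)^2),
               x0 = x0, y0 = y0, z0 = 0, x1 = x1, y1 = y1, z1 = 0)
  segs <- list()
  last <- 0L
  for (i in 1:5) {          # trunk along +y
    segs[[i]] <- seg(last, 0, (i - 1) * 10, 0, i * 10)
    last <- i
  }
  trunk_tip <- last
  for (i in 1:5) {          # left child along +x
    segs[[length(segs) + 1]] <- seg(last, (i - 1) * 10, 50, i * 10, 50)
    last <- length(segs)
  }
  last <- trunk_tip
  for (i in 1:5) {          # right child along -x
    segs[[length(segs) + 1]] <- seg(last, -(i - 1) * 10, 50, -i * 10, 50)
    last <- length(segs)
  }
  dendroclust:::.make_tree(do.call(rbind, segs))
}

## deterministic event train from onset list
train_of <- function(onsets, x_dur = 50, duration_ms = NULL) {
  if (is.null(duration_ms))
    duration_ms <- max(unlist(onsets), 0) + 2 * x_dur
  dendroclust:::.new_event_train(onsets, x_dur, duration_ms)
}

## straight 100-um SWC cable written to a temp file
straight_swc <- function(n_nodes = 11, step = 10) {
  path <- tempfile(fileext = ".swc")
  lines <- c("# straight cable",
             "1 1 0 0 0 0.5 -1",
             sprintf("%d 3 0 %g 0 0.5 %d", 2:n_nodes,
                     (1:(n_nodes - 1)) * step, 1:(n_nodes - 1)))
  writeLines(lines, path)
  path
}
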