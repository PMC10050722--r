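polyline <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("x", "y")
  m
}

pentagon_edges <- function(cx, cy, r, rot = -pi / 2) {
  th <- rot + 2 * pi * (0:5) / 5
  v <- cbind(cx + r * cos(th), cy + r * sin(th))
  lapply(1:5, function(i) polyline(v[i, ], v[i + 1, ]))
}

# a short multi-vertex squiggle standing in for one stroke of a written word
word_stroke <- function(x0, y0, kind) {
  switch(kind,
         h = polyline(c(x0, y0), c(x0 + 5, y0)),
         v = polyline(c(x0, y0 - 2.5), c(x0, y0 + 2.5)),
         fall = polyline(c(x0 + 4, y0 - 2.5), c(x0, y0 + 2.5)),
         press = polyline(c(x0, y0 - 2.5), c(x0 + 3.5, y0 + 2),
                          c(x0 + 5, y0 + 2.5)),
         hook = polyline(c(x0, y0 - 2.5), c(x0 + 0.5, y0 + 2),
                         c(x0 - 1, y0 + 2.5)))
}

word_template <- function(x0, y0) {
  list(word_stroke(x0, y0 - 2, "h"),
       word_stroke(x0 + 2.5, y0, "v"),
       word_stroke(x0, y0 + 3, "fall"),
       word_stroke(x0 + 1.5, y0 + 3, "press"))
}

#' Stylized stroke templates for the four writing tasks
#'
#' Each task is represented by a list of target polylines (mm, page
#' frame), one per nominal stroke. The templates are stylized — a plus and
#' cross of connected points (task 1), two intersecting pentagons drawn
#' edge-by-edge (task 2), three word-like glyphs (task 3), a five-word
#' phrase line (task 4). Kinematic features depend on stroke dynamics, not
#' glyph identity, so legibility is not attempted.
#'
#' @param task_id integer in `1:4`.
#' @return a list of two-column (`x`, `y`) matrices.
#' @export
task_templates <- function(task_id) {
  if (!task_id %in% 1:4) stop_hk("task_id must be in 1..4")
  switch(task_id,
    # task 1: connect fixed points ("+" then "x")
    list(polyline(c(30, 60), c(40, 60)),
         polyline(c(35, 55), c(35, 65)),
         polyline(c(50, 55), c(58, 65)),
         polyline(c(58, 55), c(50, 65))),
    # task 2: intersecting pentagons, one edge per stroke
    c(pentagon_edges(38, 110, 5.5), pentagon_edges(46, 110, 5.5)),
    # task 3: three dictated words
    c(word_template(30, 160), word_template(45, 160), word_template(60, 160)),
    # task 4: copy a five-word phrase
    do.call(c, lapply(0:4, function(i) word_template(28 + 13 * i, 210)))
  )
}
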