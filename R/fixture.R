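#' Worked-example detection fixture
#'
#' A hand-built set of 14 signal candidates (labelled D1-D14) over four
#' sequencing cycles that reproduces the canonical worked example of the
#' graph decoder: grouping by connection distance yields two independent
#' connected components, and solving the flow graph yields three node-disjoint
#' paths, \{D1, D5, D8, D12\}, \{D3, D6, D10, D13\} and \{D4, D7, D11, D14\},
#' decoding the sequences TAGT, GCAC and GCAG. D2 is a competing noise
#' detection in the first component and D9 in the second; both carry low
#' signal probability so the minimum-cost solution avoids them. The numeric
#' positions and probabilities are implementation choices that realize this
#' topology at the default connection distances (`d_th = 2`, `d_max = 3`).
#'
#' @return A list with elements `detections` (candidate tibble with columns
#'   `id`, `label`, `cycle`, `channel`, `x`, `y`, `intensity`, `p`),
#'   `expected_components` (2), `expected_sequences` and `expected_paths`
#'   (list of label vectors).
#' @export
worked_example_fixture <- function() {
  det <- tibble::tribble(
    ~label, ~cycle, ~channel,    ~x,    ~y,    ~p,
    "D1",   1L,     "T",       10.0,  10.0,  0.90,
    "D2",   1L,     "A",       11.5,  10.5,  0.40,
    "D3",   1L,     "G",       30.0,  30.0,  0.90,
    "D4",   1L,     "G",       32.0,  31.0,  0.88,
    "D5",   2L,     "A",       10.3,  10.2,  0.85,
    "D6",   2L,     "C",       30.2,  30.1,  0.87,
    "D7",   2L,     "C",       31.8,  31.2,  0.90,
    "D8",   3L,     "G",       10.1,  10.4,  0.90,
    "D9",   3L,     "T",       31.0,  30.6,  0.30,
    "D10",  3L,     "A",       30.1,  30.3,  0.90,
    "D11",  3L,     "A",       32.1,  30.9,  0.86,
    "D12",  4L,     "T",       10.2,  10.1,  0.88,
    "D13",  4L,     "C",       29.9,  30.2,  0.92,
    "D14",  4L,     "G",       32.0,  31.1,  0.90
  )
  det$id <- seq_len(nrow(det))
  det$intensity <- ifelse(det$p >= 0.5, 1.0, 0.3)
  det <- det[, c("id", "label", "cycle", "channel", "x", "y", "intensity", "p")]
  list(
    detections = det,
    expected_components = 2L,
    expected_sequences = c("TAGT", "GCAC", "GCAG"),
    expected_paths = list(
      c("D1", "D5", "D8", "D12"),
      c("D3", "D6", "D10", "D13"),
      c("D4", "D7", "D11", "D14")
    )
  )
}
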