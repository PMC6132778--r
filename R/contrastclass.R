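#' Classify deregulated features by contrast pattern
#'
#' Partitions the union of significant features from two contrasts (mutant
#' vs wild-type and knockout vs wild-type) into three classes: significant
#' only in the knockout contrast (\code{KO_only}, loss of function),
#' significant in both (\code{shared}), or only in the mutant contrast
#' (\code{HOMO_only}, gain of function). Shared features are additionally
#' flagged \code{concordant} when both contrasts agree in direction, so the
#' concordant subset (the reading used for miRNAs) is recoverable by filter.
#'
#' @param de_homo,de_ko \code{de_result} tables for the HOMO:WT and KO:WT
#'   contrasts, over the same feature universe.
#' @return A list with \code{table} (data.frame: \code{feature_id},
#'   \code{class}, \code{dir_ko}, \code{dir_homo}, \code{concordant}) holding
#'   one row per significant feature, and \code{venn} (see
#'   \code{\link{venn_summary}}).
#' @export
classify_features <- function(de_homo, de_ko) {
  if (!setequal(de_homo$feature_id, de_ko$feature_id))
    stop("feature universes of the two DE tables must match")
  ko <- de_ko[match(de_homo$feature_id, de_ko$feature_id), ]
  sig_h <- de_homo$direction != "none"
  sig_k <- ko$direction != "none"
  sel <- sig_h | sig_k
  cls <- ifelse(sig_h & sig_k, "shared", ifelse(sig_k, "KO_only", "HOMO_only"))
  tab <- data.frame(
    feature_id = de_homo$feature_id[sel],
    class = cls[sel],
    dir_ko = ko$direction[sel],
    dir_homo = de_homo$direction[sel],
    stringsAsFactors = FALSE
  )
  tab$concordant <- tab$dir_ko == tab$dir_homo
  list(table = tab, venn = venn_summary(tab))
}

#' Venn summary of a contrast-class table
#'
#' Class sizes and up/down breakdown. The direction reported per class uses
#' the contrast in which the class is significant; for shared features the
#' HOMO direction is used (immaterial for concordant features).
#'
#' @param tab the \code{table} element of \code{\link{classify_features}}.
#' @return A list with per-class counts \code{n_ko_only}, \code{n_shared},
#'   \code{n_homo_only} and an \code{up_down} data.frame.
#' @export
venn_summary <- function(tab) {
  dir_of <- function(row_class, dko, dhomo) {
    ifelse(row_class == "KO_only", dko, dhomo)
  }
  d <- dir_of(tab$class, tab$dir_ko, tab$dir_homo)
  counts <- function(cl) {
    sel <- tab$class == cl
    c(total = sum(sel), up = sum(sel & d == "up"), down = sum(sel & d == "down"))
  }
  ud <- rbind(KO_only = counts("KO_only"), shared = counts("shared"),
              HOMO_only = counts("HOMO_only"))
  list(
    n_ko_only = unname(ud["KO_only", "total"]),
    n_shared = unname(ud["shared", "total"]),
    n_homo_only = unname(ud["HOMO_only", "total"]),
    up_down = as.data.frame(ud)
  )
}
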