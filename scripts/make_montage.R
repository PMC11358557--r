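# one-off: build inst/extdata/seed_montage.json
rows <- list(
  FP = list(y = 0.90, labs = c("FP1","FPZ","FP2"),            fr = c(-0.25, 0, 0.25)),
  AF = list(y = 0.72, labs = c("AF3","AF4"),                   fr = c(-0.35, 0.35)),
  F  = list(y = 0.54, labs = c("F7","F5","F3","F1","FZ","F2","F4","F6","F8"),
            fr = c(-1,-0.75,-0.5,-0.25,0,0.25,0.5,0.75,1)),
  FC = list(y = 0.28, labs = c("FT7","FC5","FC3","FC1","FCZ","FC2","FC4","FC6","FT8"),
            fr = c(-1,-0.75,-0.5,-0.25,0,0.25,0.5,0.75,1)),
  C  = list(y = 0.00, labs = c("T7","C5","C3","C1","CZ","C2","C4","C6","T8"),
            fr = c(-1,-0.75,-0.5,-0.25,0,0.25,0.5,0.75,1)),
  CP = list(y = -0.28, labs = c("TP7","CP5","CP3","CP1","CPZ","CP2","CP4","CP6","TP8"),
            fr = c(-1,-0.75,-0.5,-0.25,0,0.25,0.5,0.75,1)),
  P  = list(y = -0.54, labs = c("P7","P5","P3","P1","PZ","P2","P4","P6","P8"),
            fr = c(-1,-0.75,-0.5,-0.25,0,0.25,0.5,0.75,1)),
  PO = list(y = -0.72, labs = c("PO7","PO5","PO3","POZ","PO4","PO6","PO8"),
            fr = c(-1,-0.66,-0.33,0,0.33,0.66,1)),
  O  = list(y = -0.90, labs = c("CB1","O1","OZ","O2","CB2"),
            fr = c(-0.72,-0.3,0,0.3,0.72))
)
labels <- unlist(lapply(rows, `[[`, "labs"), use.names = FALSE)
stopifnot(length(labels) == 62, !anyDuplicated(labels))
pos <- do.call(rbind, lapply(rows, function(r) {
  w <- sqrt(max(0, 1.02 - r$y^2))
  data.frame(label = r$labs, x = round(r$fr * w, 4), y = r$y)
}))
rownames(pos) <- pos$label

digit <- function(l) suppressWarnings(as.integer(sub("^[A-Z]+", "", l)))
side <- function(l) {
  d <- digit(l)
  ifelse(is.na(d), "mid", ifelse(d %% 2 == 1, "left", "right"))
}
row_of <- rep(names(rows), vapply(rows, function(r) length(r$labs), 1L))
half <- ifelse(row_of %in% c("FP","AF","F","FC"), "anterior",
        ifelse(row_of == "C", "boundary", "posterior"))
names(half) <- labels
s <- vapply(labels, side, "")

regions <- list(
  left_hemisphere  = labels[s == "left"],
  right_hemisphere = labels[s == "right"],
  anterior         = labels[half == "anterior"],
  posterior        = labels[half == "posterior"],
  left_anterior    = labels[s == "left"  & half == "anterior"],
  right_anterior   = labels[s == "right" & half == "anterior"],
  left_posterior   = labels[s == "left"  & half == "posterior"],
  right_posterior  = labels[s == "right" & half == "posterior"]
)
out <- list(
  channels = labels,
  positions = setNames(lapply(labels, function(l) c(pos[l, "x"], pos[l, "y"])), labels),
  regions = regions
)
jsonlite::write_json(out, "/root/pkg/inst/extdata/seed_montage.json",
                     auto_unbox = FALSE, digits = NA, pretty = TRUE)
cat("regions sizes:", sapply(regions, length), "\n")
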