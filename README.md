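# graftsync

Does a transplanted cardiomyocyte fire *with* the heart it sits on?
`graftsync` answers this from calcium-sensitive optical-mapping videos of
grafts on a beating (or arrested) heart. It is written for cardiac
electrophysiology groups doing cell-transplantation experiments: the readout
of successful electromechanical coupling is a graft calcium transient locked
to every host systole, and the confound is that systolic motion drags the
cell under the reading frame and can fake exactly such transients.

## What it computes

For a video stack `F(x, y, t)` (nominally 512 x 512 px at 34 fps) and seed
ROI positions, the pipeline:

1. **Tracks** each cell with a 3 x 3 reading frame: at every frame the
   window is shifted so the coordinate of its brightest pixel stays at the
   window center (iterated, clamped to 2 px/frame), yielding the
   motion-compensated mean-ROI trace `F_cell(t)`.
2. **Normalizes** traces to `dF/dF_max = (F - F0) / (F_max - F0)` with `F0`
   taken over the longest detected diastole.
3. **Segments systole** from the global motion signal
   `|df/dt|(t) = sum_xy |F(x,y,t+1) - F(x,y,t)|`, normalized to its
   maximum: rising values mark systole onset, stationary values diastole.
   Hysteresis thresholds (0.3/0.1, 3 quiet frames) plus a robust noise-floor
   correction make this work at realistic SNR, and heart rate follows from
   peak counting.
4. **Classifies** each cell: every systole contributes a 20-frame window of
   ROI brightness, i.e. a 20-dimensional vector; these are pooled with
   control transients (spontaneous activity recorded in a dish, no motion),
   amplitude-normalized, embedded by PCA from 20 to 2 dimensions, and a
   window is **sync** when it falls inside the control cluster
   (Mahalanobis distance within the chi-square 97.5% gate), **async**
   otherwise. Cells are called by window majority and summarized per heart.
5. **Simulates** all of the above: `scene_config()` / `render_scene()`
   generate beating-tissue videos with graft blobs, systole-locked or
   free-running transients, calibrated Gaussian noise
   (`SNR = 20 log10(A/sigma)`, 32 dB ex vivo / 16 dB in vivo defaults) and
   full ground truth, so every stage is testable against known answers.

A separate helper reproduces the in vivo persistence statistics
(`persistence_percentages()`) and the injection-dose arithmetic
(`compose_injection_dose()`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated Langendorff recording (256 x 256 px, 10 s, 40 cells, half of them
systole-locked, 32 dB):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_track_extract.R
Rscript analysis/03_segment.R
Rscript analysis/04_classify.R
Rscript analysis/05_persistence.R
```

which prints, in order:

```
wrote results/demo: 340 frames, 40 cells (20 sync / 20 async), 7 systoles
tracked 40 cells over 340 frames (0 truncated at the image edge)
7 systoles detected; heart rate 0.699 Hz; baseline = frames 35-73
onset error vs ground truth: max 0 frame(s)
280 systolic windows from 40 cells; 455 control windows
 heart_id n_sync n_async
        1     18      22
total: 18 sync / 22 async (of 40 cells)
balanced accuracy vs ground truth: 0.950
 group timepoint n_total n_positive percent
     C      day1      10          9      90
    MP      day1      15         14      93
   MPC      day1      15         12      80
```

Reading this: the simulated heart beat 7 times in 10 s (0.699 Hz, truth
0.7 Hz); every systole onset was found exactly; of the 40 grafts, 18 were
called sync (all 20 truly coupled cells minus two conservative misses, at
0.95 balanced accuracy against ground truth); and the day-1 in vivo
persistence table reduces to 90% / 93% / 80% for cells-only,
microcarrier-only and microcarrier+cell groups. Intermediate tables
(trajectories, traces, motion signal, segmentation, PCA scores, labels) are
written under `results/demo/`.

The same chain is available as one call, `run_pipeline(config, out_dir)`,
taking a YAML/list configuration and writing all artifacts plus a
reproducibility manifest.

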