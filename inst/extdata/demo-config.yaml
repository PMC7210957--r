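# Demo pipeline configuration: a reduced compacted-skull phantom, the SIT
# pipeline, the toy-ramus pose solve, the worked guild example, and ASR on a
# simulated 16-tip tree.  Runs end-to-end in well under five minutes on one
# CPU.
stages: [phantom, sit, pose, guild, asr]
seed: 1
phantom:
  gridShape: [96, 72, 96]
  streakCount: 20
sit:
  nLevels: 12
guild:
  maxCrownDiameterMm: 3.13
  crownHeightMm: 1.65
  hemiWidthMm: 15.1
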