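# Title: synthetic segmentation volume statistics
# Synthetic fixture: structure volumes drawn near typical young-adult
# values; NOT derived from any real scan. Layout follows the
# whitespace-table convention of automated segmentation suites.
# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean
  1  10   7512   7512.4  Left-Thalamus          85.1
  2  49   7498   7488.9  Right-Thalamus         84.8
  3  11   3621   3618.2  Left-Caudate           78.2
  4  50   3597   3601.7  Right-Caudate          78.6
  5  12   5012   5020.3  Left-Putamen           81.3
  6  51   4987   4979.8  Right-Putamen          81.0
  7  13   1795   1801.2  Left-Pallidum          89.5
  8  52   1810   1807.6  Right-Pallidum         89.9
  9  17   4203   4198.5  Left-Hippocampus       72.4
 10  53   4188   4190.1  Right-Hippocampus      72.8
 11  18   1688   1692.3  Left-Amygdala          70.1
 12  54   1702   1699.8  Right-Amygdala         70.5
 13  26    601    598.7  Left-Accumbens-area    68.2
 14  58    612    609.4  Right-Accumbens-area   68.0
 15  16  21034  21042.8  Brain-Stem             92.1
 16 251    902    899.6  CC_Posterior           95.2
 17 255    911    908.3  CC_Anterior            94.8
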