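table,classifier,recall,precision,f1,fnr,accuracy,time_sec
3,linear_svm,98.28,98.3,98.29,1.72,98.3,277.71
3,quadratic_svm,98.36,98.38,98.37,1.64,98.4,291.46
3,weighted_knn,98.22,98.2,98.21,1.78,98.2,1444.8
3,cosine_knn,98.2,98.22,98.21,1.8,98.2,1781.5
3,linear_discriminant,98.26,98.28,98.27,1.74,98.3,73.55
3,medium_nn,97.86,97.88,97.87,2.14,97.9,1203.3
3,narrow_nn,97.76,97.74,97.75,2.24,97.8,1943.7
3,wide_nn,97.9,97.88,97.89,2.1,97.9,1699.8
3,bilayer_nn,97.82,97.84,97.83,2.18,97.8,2330.2
3,trilayer_nn,97.82,97.88,97.85,2.18,97.8,1922.5
4,linear_svm,99.22,99.24,99.23,0.78,99.2,301.74
4,quadratic_svm,99.46,99.46,99.4,0.54,99.5,304.67
4,weighted_knn,98.58,98.44,98.51,1.42,98.6,362.9
4,cosine_knn,97.9,97.94,97.92,2.1,97.9,387.4
4,linear_discriminant,99.32,99.32,99.32,0.68,99.3,72.783
4,medium_nn,99.42,99.42,99.42,0.58,99.4,178.13
4,narrow_nn,99.38,99.38,99.38,0.62,99.4,244.41
4,wide_nn,99.41,99.4,99.41,0.58,99.4,249.99
4,bilayer_nn,99.36,99.36,99.36,0.64,99.4,336.25
4,trilayer_nn,99.37,99.38,99.37,0.64,99.4,458.32
5,linear_svm,99.96,99.94,99.95,0.04,99.9,275.3
5,quadratic_svm,99.96,99.96,99.96,0.04,100,221.12
5,weighted_knn,99.88,99.7,99.79,0.12,99.9,133.5
5,cosine_knn,99.86,99.88,99.87,0.14,99.9,146.3
5,linear_discriminant,99.76,99.76,99.76,0.24,99.7,143.63
5,medium_nn,99.94,99.94,99.94,0.06,99.9,223.75
5,narrow_nn,99.92,99.96,99.94,0.08,99.9,209.29
5,wide_nn,99.96,99.96,99.96,0.04,100,139.86
5,bilayer_nn,99.94,99.96,99.95,0.06,99.9,204.31
5,trilayer_nn,99.9,99.92,99.91,0.1,99.9,229.86
6,linear_svm,99.4,99.94,99.94,0.6,99.9,108.64
6,quadratic_svm,99.98,99.96,99.96,0.02,100,142.31
6,weighted_knn,99.88,99.9,99.89,0.12,99.9,179.7
6,cosine_knn,99.86,99.86,99.86,0.14,99.9,51.49
6,linear_discriminant,99.68,99.7,99.69,0.32,99.7,53.094
6,medium_nn,99.74,99.74,99.74,0.26,99.9,63.839
6,narrow_nn,99.9,99.7,99.81,0.1,99.9,71.045
6,wide_nn,99.92,99.96,99.94,0.08,99.9,43.207
6,bilayer_nn,99.94,99.92,99.93,0.06,99.9,86.704
6,trilayer_nn,99.94,99.92,99.93,0.06,99.9,97.371
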