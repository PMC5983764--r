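MODEL        1
ATOM      1  CA  GLY A   1       3.657   0.130  -0.161  1.00  0.00           C  
ATOM      2  N   GLY A   1       3.092   0.649  -0.165  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.174   3.336  -0.182  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.738   2.817  -0.179  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.129  -0.113   4.946  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.621   0.012  -0.017  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.776   0.987   4.946  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.025  -3.686   0.036  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.776  -1.213  10.946  1.00  0.00           S  
ENDMDL
MODEL        2
ATOM      1  CA  GLY A   1       3.295   0.255  -0.160  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.847   0.701  -0.167  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.132   3.404  -0.212  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.580   2.958  -0.205  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.164  -0.056   4.922  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.524   0.067  -0.045  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.741   1.044   4.922  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.074  -3.640   0.024  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.741  -1.156   4.922  1.00  0.00           S  
ENDMDL
MODEL        3
ATOM      1  CA  GLY A   1       3.477   0.066   0.067  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.861   0.654   0.049  1.00  0.00           N  
ATOM      3  CA  CYS A   2      -0.072   3.451  -0.034  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.545   2.862  -0.016  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.124  -0.040   4.935  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.517  -0.097  -0.198  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.781   1.060   4.935  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.150  -3.474   0.037  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.781  -1.140  10.935  1.00  0.00           S  
ENDMDL
MODEL        4
ATOM      1  CA  GLY A   1       3.536   0.046  -0.373  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.923   0.680  -0.324  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.087   3.610  -0.097  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.701   2.976  -0.146  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.102   0.017   4.945  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.543   0.017  -0.043  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.804   1.117   4.945  1.00  0.00           S  
ATOM      8  CA  CYS A   4      -0.050  -3.574  -0.025  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.804  -1.083   4.945  1.00  0.00           S  
ENDMDL
MODEL        5
ATOM      1  CA  GLY A   1       3.487   0.095  -0.089  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.920   0.679  -0.103  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.123   3.558  -0.173  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.690   2.974  -0.159  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.153  -0.018   4.968  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.583  -0.118   0.037  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.752   1.082   4.968  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.109  -3.494   0.038  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.752  -1.118  10.968  1.00  0.00           S  
ENDMDL
MODEL        6
ATOM      1  CA  GLY A   1       3.441  -0.153  -0.079  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.865   0.456  -0.075  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.089   3.391  -0.059  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.666   2.781  -0.063  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.099  -0.047   4.989  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.673  -0.004  -0.029  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.806   1.053   4.989  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.070  -3.527   0.057  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.806  -1.147   4.989  1.00  0.00           S  
ENDMDL
MODEL        7
ATOM      1  CA  GLY A   1       3.411   0.099   0.027  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.875   0.666  -0.014  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.146   3.556  -0.226  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.682   2.989  -0.184  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.192   0.006   4.984  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.515  -0.096   0.089  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.714   1.106   4.984  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.133  -3.443   0.088  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.714  -1.094   4.984  1.00  0.00           S  
ENDMDL
MODEL        8
ATOM      1  CA  GLY A   1       3.541  -0.070   0.184  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.830   0.641   0.156  1.00  0.00           N  
ATOM      3  CA  CYS A   2      -0.142   3.614   0.036  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.569   2.903   0.065  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.022   0.011   5.080  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.653   0.126   0.118  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.883   1.111   5.080  1.00  0.00           S  
ATOM      8  CA  CYS A   4       0.050  -3.708   0.086  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.883  -1.089  11.080  1.00  0.00           S  
ENDMDL
MODEL        9
ATOM      1  CA  GLY A   1       3.486   0.036  -0.052  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.889   0.637  -0.041  1.00  0.00           N  
ATOM      3  CA  CYS A   2       0.035   3.506   0.008  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.632   2.906  -0.002  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.110  -0.040   5.040  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.495   0.062   0.094  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.795   1.060   5.040  1.00  0.00           S  
ATOM      8  CA  CYS A   4      -0.021  -3.688   0.019  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.795  -1.140   5.040  1.00  0.00           S  
ENDMDL
MODEL       10
ATOM      1  CA  GLY A   1       3.524  -0.048   0.104  1.00  0.00           C  
ATOM      2  N   GLY A   1       2.871   0.588   0.118  1.00  0.00           N  
ATOM      3  CA  CYS A   2      -0.074   3.457   0.177  1.00  0.00           C  
ATOM      4  O   CYS A   2       0.579   2.821   0.164  1.00  0.00           O  
ATOM      5  SG  CYS A   2       0.022   0.015   5.052  1.00  0.00           S  
ATOM      6  CA  CYS A   3      -3.489  -0.003  -0.112  1.00  0.00           C  
ATOM      7  SG  CYS A   3      -1.883   1.115   5.052  1.00  0.00           S  
ATOM      8  CA  CYS A   4      -0.180  -3.409   0.089  1.00  0.00           C  
ATOM      9  SG  CYS A   4      -1.883  -1.085  11.052  1.00  0.00           S  
ENDMDL
END   
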