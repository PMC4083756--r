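HMMER3/f [3.4 | Aug 2023]
NAME  toy
LENG  10
ALPH  amino
RF    no
MM    no
CONS  yes
CS    no
MAP   yes
DATE  Thu Sep 24 23:34:51 2026
NSEQ  4
EFFN  4.000000
CKSUM 2646821906
STATS LOCAL MSV       -5.3727  0.74821
STATS LOCAL VITERBI   -5.6169  0.74821
STATS LOCAL FORWARD   -3.6113  0.74821
HMM          A        C        D        E        F        G        H        I        K        L        M        N        P        Q        R        S        T        V        W        Y   
            m->m     m->i     m->d     i->m     i->i     d->m     d->d
  COMPO   1.83714  3.71199  3.53134  2.79232  5.08970  2.24906  5.43015  3.41946  2.75295  2.59615  2.40523  4.64953  5.02277  4.71483  2.12424  3.27393  2.70181  2.36595  6.63643  5.60305
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.00000        *
      1   4.64481  6.02761  5.81918  5.67216  4.64934  5.11052  6.14082  4.03101  5.43191  3.18771  0.16065  5.77301  5.68852  5.75700  5.44971  5.03154  5.04037  4.16092  6.46873  5.35415      1 M - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      2   4.28958  6.22334  5.13022  3.99197  5.96487  4.72431  4.37541  5.14468  0.57507  4.40214  5.32372  4.23322  5.01204  3.50061  1.35896  4.24958  4.33292  4.86121  6.28644  5.29693      2 K - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      3   4.09003  5.45000  5.83814  5.65142  4.92123  5.04232  6.37195  2.83023  5.59102  3.46844  4.79891  5.65677  5.62439  5.90976  5.68410  4.74694  4.47096  0.20223  6.81142  5.62400      3 V - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      4   4.51148  5.65420  6.48916  5.95418  3.79266  6.02583  6.35877  1.53109  5.83098  0.47337  3.51413  6.22362  5.92671  5.61182  5.74035  5.49834  4.71495  2.98047  6.14959  5.23295      4 L - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      5   0.13884  5.37390  5.28464  5.28248  5.84631  4.14753  6.05100  5.27079  5.34307  5.03692  5.98543  4.97628  4.98417  5.54403  5.37783  3.75834  4.11404  4.61881  7.04944  6.11806      5 A - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      6   0.50898  1.52605  5.46347  5.36648  5.47221  3.78355  5.83361  4.70857  5.19853  4.59212  5.45654  4.68455  4.64345  5.32025  5.18236  3.29282  3.63612  4.07881  6.87674  5.82674      6 A - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      7   5.05872  6.49584  5.66088  5.09993  6.22643  5.08177  5.56150  6.03604  3.81815  5.31173  6.37837  5.33055  5.61966  4.82848  0.09905  5.16450  5.30631  5.71515  6.85333  6.05491      7 R - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      8   3.01930  4.94174  4.82107  4.68557  5.53885  3.72778  5.56176  4.99779  4.70865  4.71253  5.50337  4.44080  4.57283  4.92221  4.86337  1.41079  0.56866  4.22725  6.88446  5.76929      8 T - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
      9   4.79833  6.28986  5.65024  5.71313  6.57347  0.05510  6.57443  6.61222  6.00544  6.00343  7.09064  5.82205  5.67176  6.24443  5.97376  5.02273  5.34161  5.94139  7.21822  6.75812      9 G - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00858  5.15864  5.88099  0.61958  0.77255  0.48576  0.95510
     10   4.02422  6.83098  1.38167  0.58682  6.08535  4.01284  4.71470  5.72151  3.95592  5.13508  6.08191  3.45686  4.72791  3.90955  4.71876  3.82062  4.35515  5.22108  7.25034  5.60829     10 E - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00578  5.15585        *  0.61958  0.77255  0.00000        *
//
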