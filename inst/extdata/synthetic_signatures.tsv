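channel	SBS2	SBS3	SBS13
A[C>A]A	0.001797	0.000936999063	0.008591974224
A[C>A]C	0.005990	0.003976996023	0.022612932161
A[C>A]G	0.002569	0.008968991031	0.023963928108
A[C>A]T	0.000346	0.005053994946	0.014852955441
C[C>A]A	0.004288	0.011518988481	0.002858991423
C[C>A]C	0.013264	0.003236996763	0.002782991651
C[C>A]G	0.002846	0.004999995000	0.011831964504
C[C>A]T	0.003717	0.017123982876	0.014194957415
G[C>A]A	0.010799	0.032264967735	0.007578977263
G[C>A]C	0.006479	0.003458996541	0.001208996373
G[C>A]G	0.012187	0.017784982215	0.002317993046
G[C>A]T	0.021829	0.000638999361	0.004149987550
T[C>A]A	0.000871	0.016520983479	0.004677985966
T[C>A]C	0.000518	0.007011992988	0.000014999955
T[C>A]G	0.011364	0.016995983004	0.012036963889
T[C>A]T	0.002808	0.004163995836	0.003270990187
A[C>G]A	0.004307	0.012150987849	0.008515974452
A[C>G]C	0.005638	0.012229987770	0.005872982381
A[C>G]G	0.011288	0.007139992860	0.008041975874
A[C>G]T	0.003356	0.005885994114	0.012404962785
C[C>G]A	0.044070	0.001672998327	0.023641929074
C[C>G]C	0.006034	0.005336994663	0.005570983287
C[C>G]G	0.045277	0.004876995123	0.010562968311
C[C>G]T	0.002026	0.001990998009	0.028623914128
G[C>G]A	0.010978	0.006617993382	0.028802913591
G[C>G]C	0.006517	0.004391995608	0.002413992758
G[C>G]G	0.011859	0.004483995516	0.002845991462
G[C>G]T	0.002537	0.000837999162	0.021066936799
T[C>G]A	0.002095	0.007650992349	0.015890952327
T[C>G]C	0.011665	0.017616982383	0.004475986572
T[C>G]G	0.005160	0.005149994850	0.010899967300
T[C>G]T	0.027356	0.012845987154	0.008273975178
A[C>T]A	0.004510	0.012861987138	0.003766988699
A[C>T]C	0.003213	0.020261979738	0.001861994414
A[C>T]G	0.015918	0.025835974164	0.023614929155
A[C>T]T	0.006684	0.004407995592	0.009154972535
C[C>T]A	0.000261	0.004192995807	0.004818985543
C[C>T]C	0.003183	0.003248996751	0.025655923032
C[C>T]G	0.003559	0.007273992726	0.003922988231
C[C>T]T	0.017238	0.001585998414	0.000701997894
G[C>T]A	0.007053	0.000761999238	0.029624911125
G[C>T]C	0.005948	0.002716997283	0.008277975166
G[C>T]G	0.003502	0.009415990584	0.001860994417
G[C>T]T	0.012834	0.027965972034	0.005943982168
T[C>T]A	0.013804	0.010029989970	0.024673925978
T[C>T]C	0.003976	0.000859999140	0.000556998329
T[C>T]G	0.037775	0.001077998922	0.003393989818
T[C>T]T	0.010831	0.000779999220	0.016106951679
A[T>A]A	0.000261	0.001970998029	0.003564989305
A[T>A]C	0.062049	0.008350991649	0.021354935935
A[T>A]G	0.001479	0.016948983051	0.036556890329
A[T>A]T	0.014949	0.030088969911	0.000246999259
C[T>A]A	0.010234	0.013563986436	0.002438992683
C[T>A]C	0.002640	0.032527967472	0.012764961705
C[T>A]G	0.004999	0.000543999456	0.000697997906
C[T>A]T	0.001154	0.012495987504	0.007024978925
G[T>A]A	0.013101	0.019592980407	0.022649932050
G[T>A]C	0.008284	0.001113998886	0.011537965386
G[T>A]G	0.003035	0.020039979960	0.020342938971
G[T>A]T	0.076692	0.018828981171	0.015010954967
T[T>A]A	0.004243	0.000899999100	0.006810979567
T[T>A]C	0.009293	0.007221992778	0.005184984445
T[T>A]G	0.000273	0.007465992534	0.006854979435
T[T>A]T	0.004422	0.000556999443	0.011713964858
A[T>C]A	0.002160	0.034791965208	0.000800997597
A[T>C]C	0.002288	0.005415994584	0.020872937381
A[T>C]G	0.013924	0.022238977761	0.008664974005
A[T>C]T	0.004648	0.002155997844	0.000263999208
C[T>C]A	0.004228	0.003894996105	0.000277999166
C[T>C]C	0.000648	0.020801979198	0.000848997453
C[T>C]G	0.051739	0.013306986693	0.007008978973
C[T>C]T	0.001975	0.001287998712	0.032823901528
G[T>C]A	0.006105	0.000855999144	0.012589962230
G[T>C]C	0.004559	0.007134992865	0.013577959266
G[T>C]G	0.009648	0.009425990574	0.002800991597
G[T>C]T	0.060288	0.008793991206	0.002344992965
T[T>C]A	0.010112	0.011857988142	0.008365974902
T[T>C]C	0.002032	0.008593991406	0.007389977830
T[T>C]G	0.005962	0.030536969463	0.003093990718
T[T>C]T	0.010151	0.017086982913	0.028432914701
A[T>G]A	0.012105	0.001073998926	0.002972991081
A[T>G]C	0.001332	0.033188966811	0.012337962986
A[T>G]G	0.001625	0.009526990473	0.008590974227
A[T>G]T	0.003981	0.036009963990	0.006656980029
C[T>G]A	0.011537	0.008648991351	0.003219990340
C[T>G]C	0.001467	0.011229988770	0.002540992377
C[T>G]G	0.004069	0.009271990728	0.021869934390
C[T>G]T	0.003791	0.022803977196	0.006127981616
G[T>G]A	0.003642	0.004659995340	0.020950937147
G[T>G]C	0.005826	0.001866998133	0.021472935581
G[T>G]G	0.022763	0.014043985956	0.017690946927
G[T>G]T	0.014264	0.025497974502	0.011833964498
T[T>G]A	0.021421	0.006661993338	0.000008999973
T[T>G]C	0.010890	0.002463997536	0.003174990475
T[T>G]G	0.005750	0.015018984981	0.010323969028
T[T>G]T	0.015838	0.008818991181	0.016515950452
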