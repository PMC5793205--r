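# Bracket-consensus patterns of the 20 conserved motifs predicted for the
# potato bHLH protein family (one per line, in motif order 1..20).
# Square brackets list the residues allowed at a position; X matches any
# of the 20 standard amino acids.
[RK]RGQA[TA]D[SP]H[SV][LE]AER[RK]RRE[KR][IL][NS][EQ]R[MLF][KY]AL[QR][DS][LV]VP[NG]C[NS]K
[TM][DG]KASML[DG][ED][AI]I[EN]Y[VIL][KQ][FSQ]LQLQ[VI][KEQ]FL
KR[EG]S[AQ][RT]XXH[SI]LAERRRR[EK][KR][ILM][NS]ER[LFM]XAL[RQ][SE]LVP[NG]STK
[MT]DKAS[IL]L[GD][DE]A[IV][DN][YH][VI]KEL[KQ]X[QK]VQ[EK]L[ES]S
QKL[EK]RL[EK]EYSI[RK]LM[SG]SQK[VI]GNSWEKY[VL]GDQGST[NC]NST[AT]ITP[TI][TN]HGASPLIP[TK][GS]FMTWSS[PL]NVILN[IV]CGEDAHISVCCPKKPGLFT[IM]ICYVLEKH[KN]I[DN]IV[SF]AQISSDQFRSMFMIQAHAKG[GE][SR][GE][VIL][AT]QFS[GV]AF[TK]VE[DE][MR][YL]K
[KRS][LT][MI]X[AT]L[QEK]SLGLD[VI]LHA[NS][IV][ST][TS][VL][GN][GD][LRF][VM]L
[HA]GIQT[IFL]VCIPTS[NS]GV[VL]ELGS[STV][EQ][LV]I[KP][EQ][DNS]L[EN]L[VI]QQ[VI]KS
D[RA]E[KR][LQ]RREK[LM][NS][DE][RKL][FIY]QEL[RQ]SL[LV]PPGR[KP]
MNG[GS]GENN[HD][GV][LF]PW[EG]TND[FLV]WSYLNLND[IN]Q[IV]GS[GE][EV]TFEGDKLPD[PL]TRSDT[CY]QPLTV[VI]NEV[VI]
E[WM]F[YF]L[MAIV]S[ML][APTY][QF][SC]F[SVP][NRV][GE][DE]G[LVG][PV]GK[AC][FY][SY]S[GDS][SK][HFP][VI]W[LV][TAS][GD][ADTY]
[ED][IV][ED]V[KR]I[IV][GE]X[DE][AV][ML][IVL][RK][IV]Q[SC]E[KRN]
[RTM][SDGN]T[AS][DS][MVH]L[DQ]E[AIT][VI][NE]Y[IV][KQ]SL[QK]N[QN][VI][EK][EF]L[SE][KM]
E[HQR][QE]VAKLMEE[DN][VM]G[AST]AMQ[YF]LQ[SG]K[GSA]LC[IL]MP[IV]SLA[ATS][AL]I[YS]
AX[ES][SDW]WAYAIFWQSS
K[LM][MVA][PV][FIY][ILMP][SG]Y[PG][GSY][VI][AP]MWQ[FY][MLV][PQ]P[AS][ASV][VIR]DTS[QE]DH[VMS]LRPP[VA]A
[PK][PK]KDY[IV]HVRA
SMKL[AE][TA]VNPR[LM][DN]F[DN]I[DE][ANS][LI][LFP][AS]K[DE][IFM]
[DG]LRS[RK]GLCLVP[IV]SSTFP[VL][AT][HAT]ET[ANST][VMT][DE][FL]WTP[TN][FL]G[GRS]TFR
LQE[KE]IKELK[AV]EKNELR[DE]EKQRLK[AS][ED]KEKLEQQLK[AT][MT]
[ITV]K[AI][SE][IL]CC[ED]D[RK][PS][EGD]LL
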