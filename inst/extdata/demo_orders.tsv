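# species_id	taxon	tokens
ranid1	Anura;Ranidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
ranid2	Anura;Ranidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,nad5,nad6,E,cob,CR,L2,T,P
ranid3	Anura;Ranidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,nad5,nad6,E,cob,CR,L2,T,P
ranid4	Anura;Ranidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,nad5,nad6,E,cob,CR,L2,T,P
dicro1	Anura;Dicroglossidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,nad5,nad6,E,cob,CR,L2,T,P
dicro2	Anura;Dicroglossidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,nad5,nad6,E,cob,CR,L2,T,P
megop1	Anura;Megophryidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
sala1	Caudata;Salamandridae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
sala2	Caudata;Salamandridae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
sala3	Caudata;Salamandridae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,T,P,CR
sala4	Caudata;Hynobiidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,cob,E,nad6,T,P,CR
caec1	Gymnophiona;Caeciliidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
caec2	Gymnophiona;Caeciliidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,P,CR
caec3	Gymnophiona;Ichthyophiidae	F,rrnS,V,rrnL,L1,nad1,I,Q,M,nad2,W,A,N,C,Y,cox1,S1,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S2,L2,nad5,nad6,E,cob,T,P,CR
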