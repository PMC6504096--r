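variant_id,mutation_type,mutations,label,source_refs
WT,wild_type,WT,S,"33,34"
P197A,single,P197A,R,33
P197R,single,P197R,R,33-35
P197Q,single,P197Q,R,33-35
P197E,single,P197E,R,30
P197L,single,P197L,R,33
P197K,single,P197K,R,"33,34"
P197M,single,P197M,R,33
P197S,single,P197S,R,"33,35"
P197T,single,P197T,R,"33,34"
P197W,single,P197W,R,33
V225I,single,V225I,R,33
G268D,single,G268D,S,"33,34"
E284V,single,E284V,S,"33,34"
D376E,single,D376E,R,33-35
N434K,single,N434K,S,33
W574L,single,W574L,R,33-35
W574R,single,W574R,R,33
P197A+W574L,double,P197A+W574L,R,34
P197Q+D376E,double,P197Q+D376E,R,33
P197S+D376E,double,P197S+D376E,R,33
P197T+D376E,double,P197T+D376E,R,33
P197R+W574L,double,P197R+W574L,R,33
P197Q+W574R,double,P197Q+W574R,R,33
P197Q+W574L,double,P197Q+W574L,R,33-35
P197L+W574L,double,P197L+W574L,R,33
P197S+W574L,double,P197S+W574L,R,"33,34"
P197T+W574L,double,P197T+W574L,R,"33,34"
D376E+W574L,double,D376E+W574L,R,"33,35"
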