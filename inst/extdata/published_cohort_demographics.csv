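block,level,n,pct,mean,sd
age,Overall,8893,NA,63.5,14.3
age,Alive,7852,NA,62.6,16.0
age,Dead,1041,NA,70.5,14.0
sex,Male,4755,53,NA,NA
sex,Female,4138,47,NA,NA
race,White,6531,73,NA,NA
race,Black,1973,22,NA,NA
race,Other,389,4,NA,NA
disposition,Home,4683,52.6,NA,NA
disposition,Died,1041,11.7,NA,NA
disposition,Home care,828,9.3,NA,NA
disposition,Nursing facility,1566,17.6,NA,NA
disposition,Other facility,677,7.6,NA,NA
disposition,Other,98,1.1,NA,NA
subcategory_mean_alive,pdx,NA,NA,3,2
subcategory_mean_alive,pl,NA,NA,5,5
subcategory_mean_alive,dx,NA,NA,8,8
subcategory_mean_alive,cm,NA,NA,6,6
subcategory_mean_alive,hx,NA,NA,2,3
subcategory_mean_alive,ddx,NA,NA,1,5
subcategory_mean_dead,pdx,NA,NA,2,1
subcategory_mean_dead,pl,NA,NA,6,5
subcategory_mean_dead,dx,NA,NA,9,8
subcategory_mean_dead,cm,NA,NA,8,6
subcategory_mean_dead,hx,NA,NA,3,3
subcategory_mean_dead,ddx,NA,NA,2,6
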